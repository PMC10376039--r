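# empisim

Empirical-similarity predictive models for small datasets with categorical
and ordinal covariates, with a Monte Carlo sensitivity-analysis protocol
for comparing them — against each other and against ordinary linear
regression — by the variability of their parameter estimators.

## Who this is for

Analysts of small designed experiments (the running example is the classic
60-observation guinea-pig tooth-growth study: tooth length vs vitamin C
dose ∈ {0.5, 1, 2} mg and supplement type VC/OJ) who want a
prediction method that makes no functional-form assumption, and who need to
know how sensitive its estimated parameters are to the train/test split.

## The model

The response at covariates $x_t$ is a similarity-weighted average of the
other observed responses,

$$\hat Y_t = \frac{\sum_{i \ne t} s(x_i, x_t)\, y_i}{\sum_{i \ne t} s(x_i, x_t)},$$

with kernel $s = e^{-d_w}$ (EX) or $s = 1/(1+d_w)$ (FR) and a weighted
covariate distance $d_w$: binary $(\sum_l w_l 1[x_l \ne x'_l])^\delta$
(WBD), squared Euclidean $(\sum_l w_l (x_l-x'_l)^2)^\delta$ (WED), or
Minkowski $(\sum_l w_l |x_l-x'_l|^\gamma)^{1/\gamma}$ (WMD). Categorical
covariates are handled either in original form with one weight per
covariate (**M1**) or one-hot encoded with one weight per level (**M2**,
Euclidean distance only). The non-negative weights are estimated by
leave-one-out least squares (**OLS**) or by a sequential Gaussian
likelihood (**ML**), from five data-driven starts, keeping the fit with
minimal test-set MSE. The sensitivity protocol repeats a random 70/30
split 30 times and reports the coefficient of variation (CV = sd/|mean|)
of every weight estimator and the test MSE per scenario of the
model × method × kernel × distance × exponent grid (57 scenarios by
default). See the vignette (`vignettes/empirical-similarity.Rmd`) for the
full account.

## Worked example

Fit M1 with the binary distance (δ = 4), exponential kernel and ML on one
70/30 split of the real data:

```r
library(empisim)
data <- tooth_growth()                      # n = 60, covariates dose + supp
sp    <- split_train_test(data$n, 0.7, seed = 1)
train <- subset_rows(data, sp$train)
test  <- subset_rows(data, sp$test)
spec  <- model_spec("M1", distance_spec("wbd", delta = 4), similarity_spec("ex"))
fit   <- fit_multistart(train, test, spec, "ml", initial_starts(train, "M1"))
fit
#> Empirical-similarity fit (ML)
#>   weights: 10.529, 16.505
#>   objective: 132.124 (-log-likelihood)
#>   sigma2: 31.619  alpha: 18.167
#>   start: 1
#>   converged: TRUE  evals: 6
```

The two weights are the dose and supplement distance weights: how strongly
a difference in dose (resp. supplement) downweights a neighbour's
contribution. `alpha` is the sample-mean anchor of the sequential
likelihood and `sigma2` its profiled error variance.

Sensitivity of the M2 weights under ML + EX at δ = 2, over 30 splits:

```r
sc  <- scenario_grid(models = "M2", deltas = 2, methods = "ml", similarities = "ex")
res <- run_sensitivity(data, sc, R = 30, base_seed = 20230)
round(res$summaries$M2_WED_d2_ML_EX$cv_per_weight, 4)
#> dose_0.5   dose_1   dose_2     supp
#>   0.0436   0.0491   0.0480   0.0410
round(res$summaries$M2_WED_d2_ML_EX$mean_mse, 2)
#> [1] 14.75
```

A CV of 0.04–0.05 means each weight estimate varies by about 4–5% of its
mean across random splits; the mean test MSE of ~14.8 is on the squared
scale of tooth length. `write_sensitivity(res, dir)` exports tidy
`cv_summary.csv`, `mse_summary.csv` and `iterations.csv`, and
`run_from_config()` (or the CLI wrapper `inst/cli/empisim.R`) drives the
whole workflow from a YAML configuration.

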