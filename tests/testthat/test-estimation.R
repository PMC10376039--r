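ml_spec <- function(sim = "ex", kind = "wed", delta = 1, gamma = 1,
                    approach = "M1")
  model_spec(approach,
             if (kind == "wmd") distance_spec(kind, gamma = gamma)
             else distance_spec(kind, delta = delta),
             similarity_spec(sim))

test_that("the five starts follow the cell-mean recipe for M1 and M2", {
  # placeholders: ybar11..13 = 10, 20, 26; ybar21..22 = 17, 21
  cov <- data.frame(dose = c(0.5, 1, 2, 0.5, 1, 2),
                    supp = c(0, 0, 0, 1, 1, 1))
  # solve for responses giving those level means:
  # dose means over both supp rows, supp means over three dose rows
  y <- c(6, 16, 22, 14, 24, 30)
  d <- es_dataset(cov, y, tooth_schema())
  cm <- cell_means(d)
  expect_equal(unname(cm$dose), c(10, 20, 26))
  expect_equal(unname(cm$supp), c(44 / 3, 68 / 3))
  s1 <- initial_starts(d, "M1")
  expect_length(s1$starts, 5)
  expect_equal(s1$starts[[1]], c(10, 44 / 3))
  expect_equal(s1$starts[[2]], c(10, 68 / 3))
  expect_equal(s1$starts[[3]], c(20, 44 / 3))
  expect_equal(s1$starts[[4]], c(20, 68 / 3))
  expect_equal(s1$starts[[5]], c(26, 44 / 3))
  s2 <- initial_starts(d, "M2")
  expect_equal(s2$starts[[1]], c(10, 10, 10, 44 / 3))
  expect_equal(s2$starts[[5]], c(26, 26, 26, 44 / 3))
  # constant response: all starts are constant vectors
  dc <- es_dataset(cov, rep(5, 6), tooth_schema())
  expect_true(all(vapply(initial_starts(dc, "M2")$starts,
                         function(s) all(s == 5), logical(1))))
  # non-demo schema is refused with a pointer to explicit starts
  d1 <- toy_dataset_1d(c(0, 1, 0, 1), 1:4)
  expect_error(initial_starts(d1, "M1"), "explicit starts")
})

test_that("least-squares fit beats an exhaustive grid and its own start", {
  d <- toy_tooth(reps = 2, sigma = 3, seed = 14)
  spec <- ml_spec("fr", "wed")
  grid <- as.matrix(expand.grid(w1 = seq(0, 10, 0.5), w2 = seq(0, 10, 0.5)))
  sse <- apply(grid, 1, function(w) naive_loo_sse(d, w, "wed", "fr"))
  best <- which.min(sse)
  fit <- fit_ols(d, spec, start = grid[best, ])
  expect_s3_class(fit, "es_fit")
  expect_lte(fit$objective, sse[best] + 1e-6)
  # reported objective equals the SSE recomputed from scratch
  expect_equal(fit$objective, sum(residuals_loo(d, fit$weights, spec)^2),
               tolerance = 1e-8)
  # descent contract from an arbitrary start
  st <- c(4, 7)
  fit2 <- fit_ols(d, spec, start = st)
  expect_lte(fit2$objective, naive_loo_sse(d, st, "wed", "fr") + 1e-8)
  expect_true(all(fit2$weights >= 0))
})

test_that("constant-response data leaves the least-squares start unchanged", {
  cov <- data.frame(dose = rep(c(0.5, 1, 2), 2), supp = rep(c(0, 1), 3))
  d <- es_dataset(cov, rep(3, 6), tooth_schema())
  fit <- fit_ols(d, ml_spec(), start = c(2, 5))
  expect_equal(fit$objective, 0)
  expect_equal(fit$weights, c(2, 5))
})

test_that("ML fit matches a dense 1-weight grid of the profiled likelihood", {
  x <- rep(c(0, 1, 2), 4)
  set.seed(2)
  d <- toy_dataset_1d(x, 2 * x + rnorm(12, 0, 0.5))
  spec <- ml_spec("fr")
  wgrid <- seq(0, 20, length.out = 1000)
  nll <- vapply(wgrid, function(w) naive_seq_nll(d, w, "wed", "fr"),
                numeric(1))
  fit <- fit_ml(d, spec, start = wgrid[which.min(nll)])
  expect_lte(fit$objective, min(nll) + 1e-6)
  expect_equal(fit$alpha, mean(d$response))
  # sigma2 is the profiled variance at the optimum
  e <- residuals_sequential(d, fit$weights, spec)
  expect_equal(fit$sigma2,
               ((d$response[1] - mean(d$response))^2 + sum(e^2)) / d$n,
               tolerance = 1e-10)
})

test_that("ML optimum is locally optimal to 1% weight perturbations", {
  d <- toy_tooth(reps = 2, sigma = 3, seed = 33)
  spec <- ml_spec("fr")
  fit <- fit_ml(d, spec, start = c(1, 1))
  for (j in 1:2) for (f in c(0.99, 1.01)) {
    w <- fit$weights; w[j] <- w[j] * f
    expect_gte(naive_seq_nll(d, w, "wed", "fr"), fit$objective - 1e-6)
  }
})

test_that("a perfect ML fit reports the degenerate-variance sentinel", {
  cov <- data.frame(dose = rep(c(0.5, 1, 2), 2), supp = rep(c(0, 1), 3))
  d <- es_dataset(cov, rep(3, 6), tooth_schema())
  fit <- fit_ml(d, ml_spec(), start = c(1, 1))
  expect_true(fit$converged)
  expect_equal(fit$objective, -Inf)
  expect_equal(fit$alpha, 3)
  expect_lte(fit$sigma2, 1e-12)
})

test_that("a delta below one triggers the convergence warning", {
  d <- toy_tooth(reps = 2, sigma = 3, seed = 3)
  expect_warning(fit_ols(d, ml_spec(delta = 0.5), start = c(1, 1)),
                 "delta < 1")
})

test_that("multistart selects the minimal test MSE with index tie-break", {
  d <- toy_tooth(reps = 3, sigma = 3, seed = 8)
  sp <- split_train_test(d$n, 0.7, 4)
  train <- subset_rows(d, sp$train); test <- subset_rows(d, sp$test)
  spec <- ml_spec("fr")
  starts <- list(c(1, 1), c(0.2, 5), c(8, 0.5), c(3, 3), c(10, 10))
  fit <- fit_multistart(train, test, spec, "ols", starts)
  # recompute all five test MSEs by brute force
  mses <- vapply(starts, function(s) {
    f <- fit_ols(train, spec, s)
    preds <- vapply(seq_len(test$n), function(i)
      predict_one(test$covariates[i, , drop = FALSE], train, f$weights,
                  spec)$value, numeric(1))
    mean((preds - test$response)^2)
  }, numeric(1))
  expect_equal(fit$start_mses, mses, tolerance = 1e-10)
  expect_equal(fit$test_mse, min(mses))
  expect_equal(fit$start_index, which.min(mses))
  # identical starts: the tie goes to start 1
  fit1 <- fit_multistart(train, test, spec, "ols",
                         replicate(5, c(1, 1), simplify = FALSE))
  expect_equal(fit1$start_index, 1L)
})
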