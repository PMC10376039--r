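# Shared fixtures and independent naive oracles. The oracles deliberately
# use plain loops and textbook formulas, not the package's vectorised paths.

toy_schema_1d <- function(levels = c(0, 1)) {
  covariate_schema("x", "ordinal", list(x = levels))
}

toy_dataset_1d <- function(x, y) {
  es_dataset(data.frame(x = x), y, toy_schema_1d(sort(unique(x))))
}

# small balanced tooth-like dataset: 2 rows per cell, deterministic response
toy_tooth <- function(reps = 2, sigma = 2, seed = 42) {
  generate_toothlike(sigma = sigma, reps_per_cell = reps, seed = seed)
}

# naive distance between two covariate rows
naive_distance <- function(x, xp, w, kind, delta = 1, gamma = 1) {
  if (kind == "wbd") return(sum(w * (x != xp))^delta)
  if (kind == "wed") return(sum(w * (x - xp)^2)^delta)
  sum(w * abs(x - xp)^gamma)^(1 / gamma)
}

naive_similarity <- function(d, kind) if (kind == "ex") exp(-d) else 1 / (1 + d)

# naive similarity prediction of row t of X/y from the pool rows in `pool`
naive_predict <- function(t, pool, X, y, w, dk, sk, delta = 1, gamma = 1) {
  s <- vapply(pool, function(i)
    naive_similarity(naive_distance(X[i, ], X[t, ], w, dk, delta, gamma), sk),
    numeric(1))
  sum(s * y[pool]) / sum(s)
}

# naive leave-one-out SSE (the least-squares estimation objective)
naive_loo_sse <- function(data, w, dk, sk, delta = 1, gamma = 1) {
  X <- as.matrix(data$covariates)
  y <- data$response
  sum(vapply(seq_len(data$n), function(t) {
    (y[t] - naive_predict(t, setdiff(seq_len(data$n), t), X, y, w, dk, sk,
                          delta, gamma))^2
  }, numeric(1)))
}

# naive profiled negative log-likelihood of the sequential model
naive_seq_nll <- function(data, w, dk, sk, delta = 1, gamma = 1) {
  X <- as.matrix(data$covariates)
  y <- data$response
  n <- data$n
  e <- vapply(2:n, function(t)
    y[t] - naive_predict(t, seq_len(t - 1), X, y, w, dk, sk, delta, gamma),
    numeric(1))
  s2 <- ((y[1] - mean(y))^2 + sum(e^2)) / n
  n / 2 * (log(2 * pi * s2) + 1)
}
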