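#' Design matrix for the linear benchmark
#'
#' Builds the fixed-effects design used by the ordinary-regression benchmark:
#' an intercept, then for every covariate with k > 2 declared levels the
#' k - 1 indicator columns of its non-reference levels (reference = first
#' schema level), then binary covariates as they stand. For the tooth-growth
#' schema this yields 4 columns (intercept, dose 1.0, dose 2.0, supp) — the
#' same parameter count as the one-hot similarity model M2.
#'
#' @param data An `es_dataset`.
#' @return A numeric matrix with named columns.
#' @export
design_matrix <- function(data) {
  stopifnot(inherits(data, "es_dataset"))
  schema <- data$schema
  cols <- list("(Intercept)" = rep(1, data$n))
  for (j in seq_along(schema$names)) {
    nm <- schema$names[j]
    if (schema$kinds[j] == "binary") {
      cols[[nm]] <- as.numeric(data$covariates[[nm]])
    } else {
      lv <- schema_levels(schema, nm)
      if (is.null(lv))
        stop("covariate '", nm, "' has no declared levels for factor coding",
             call. = FALSE)
      for (l in lv[-1L])
        cols[[paste0(nm, format(l, trim = TRUE))]] <-
          as.numeric(data$covariates[[nm]] == l)
    }
  }
  do.call(cbind, cols)
}

#' Fit the linear regression benchmark
#'
#' Closed-form ordinary least squares on the design of [design_matrix()]:
#' coefficients (X'X)^{-1} X'y (which is also the maximum-likelihood
#' estimator under Gaussian errors), residual variance SSE / (n - p), and
#' the stored (X'X)^{-1} needed for prediction variances.
#'
#' @param data An `es_dataset` with full-column-rank design.
#' @return An object of class `linear_fit`: `coefficients`, `design_labels`,
#'   `sigma2`, `xtx_inverse`, `n`, `schema`.
#' @export
fit_lm <- function(data) {
  stopifnot(inherits(data, "es_dataset"))
  X <- design_matrix(data)
  y <- data$response
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  xtx_inv <- solve(crossprod(X))
  coef <- drop(xtx_inv %*% crossprod(X, y))
  sse <- sum((y - drop(X %*% coef))^2)
  structure(list(coefficients = coef, design_labels = colnames(X),
                 sigma2 = if (data$n > p) sse / (data$n - p) else 0,
                 xtx_inverse = xtx_inv, n = data$n, schema = data$schema),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear benchmark fit (closed form)\n")
  print(stats::setNames(round(x$coefficients, 5), x$design_labels))
  cat("sigma2:", format(x$sigma2, digits = 5), "\n")
  invisible(x)
}

# encode one covariate row into the fit's design vector
design_row <- function(fit, target) {
  target <- as.data.frame(target)
  schema <- fit$schema
  x <- c("(Intercept)" = 1)
  for (j in seq_along(schema$names)) {
    nm <- schema$names[j]
    v <- target[[nm]][1L]
    if (is.null(v)) stop("target lacks covariate '", nm, "'", call. = FALSE)
    if (schema$kinds[j] == "binary") {
      x[nm] <- as.numeric(v)
    } else {
      lv <- schema_levels(schema, nm)
      if (!(v %in% lv))
        stop("unseen level '", v, "' for covariate '", nm, "'",
             call. = FALSE)
      for (l in lv[-1L])
        x[paste0(nm, format(l, trim = TRUE))] <- as.numeric(v == l)
    }
  }
  x[fit$design_labels]
}

#' Predict from the linear benchmark
#'
#' @param fit A `linear_fit`.
#' @param target One covariate row (1-row data frame or named list)
#'   conforming to the fit's schema.
#' @return A list with `value` (x' beta-hat) and `variance`
#'   (sigma2 * x' (X'X)^{-1} x, the sampling variance of the predicted
#'   mean).
#' @export
predict_lm <- function(fit, target) {
  stopifnot(inherits(fit, "linear_fit"))
  x <- design_row(fit, target)
  list(value = drop(crossprod(x, fit$coefficients)),
       variance = fit$sigma2 * drop(crossprod(x, fit$xtx_inverse %*% x)))
}
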