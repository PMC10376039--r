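#' Specify an empirical-similarity model
#'
#' Couples the covariate-handling approach with a distance and a similarity
#' kernel. `"M1"` keeps categorical covariates in their original form, one
#' weight per covariate, and admits any of the three distances. `"M2"`
#' expects an [encode_m2()]-style all-binary dataset, one weight per level,
#' and admits the weighted Euclidean distance only.
#'
#' @param approach `"M1"` or `"M2"`.
#' @param distance A [distance_spec()].
#' @param similarity A [similarity_spec()].
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("M1", distance_spec("wbd", delta = 4), similarity_spec("ex"))
#' @export
model_spec <- function(approach = c("M1", "M2"), distance, similarity) {
  approach <- match.arg(toupper(approach), c("M1", "M2"))
  stopifnot(inherits(distance, "distance_spec"),
            inherits(similarity, "similarity_spec"))
  if (approach == "M2" && distance$kind != "wed")
    stop("M2 admits the weighted Euclidean distance only", call. = FALSE)
  structure(list(approach = approach, distance = distance,
                 similarity = similarity),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(x$approach, "/", toupper(x$distance$kind),
      if (x$distance$kind == "wmd") paste0("gamma=", x$distance$gamma)
      else paste0("delta=", x$distance$delta),
      "/", toupper(x$similarity$kind), "\n")
  invisible(x)
}

check_m2_data <- function(data, spec) {
  if (spec$approach == "M2" && any(data$schema$kinds != "binary"))
    stop("M2 requires an all-binary (one-hot encoded) dataset; ",
         "call encode_m2() first", call. = FALSE)
  invisible(data)
}

# floor below which the total similarity mass is treated as underflowed
.mass_floor <- 1e-300

# batch predictor: one prediction per row of target_X, pool given by pool_X/y.
# mask (optional, n_pool x n_target): 1 = pool row eligible for that target.
predict_core <- function(target_X, pool_X, y, w, spec, mask = NULL,
                         floor = .mass_floor) {
  terms <- pairwise_terms(pool_X, target_X, spec$distance)
  d <- terms_to_distance(terms, w, spec$distance, nrow(pool_X),
                         nrow(target_X))
  S <- similarity_kernel(d, spec$similarity)           # n_pool x n_target
  if (!is.null(mask)) S <- S * mask
  mass <- colSums(S)
  # centring the responses keeps the weighted average exact for constant y
  ybar <- mean(y)
  vals <- ybar + drop(crossprod(S, y - ybar)) / mass
  fb <- !is.finite(vals) | mass < floor
  if (any(fb)) {
    pm <- if (is.null(mask)) rep(mean(y), ncol(S))
          else drop(crossprod(mask, y)) / colSums(mask)
    vals[fb] <- pm[fb]
  }
  list(values = vals, mass = mass, fallback = fb)
}

#' Similarity-weighted prediction for one target row
#'
#' Predicts the response at a target covariate row as the similarity-weighted
#' average of the pool responses: each pool observation contributes its
#' response with weight s(x_i, x_t), the kernel similarity of its covariates
#' to the target. If the total similarity mass underflows below `floor`
#' (possible for the exponential kernel with strongly inflated distances),
#' the pool mean response is returned and flagged.
#'
#' @param target A single covariate row: a 1-row data frame (or named list)
#'   conforming to the pool schema.
#' @param pool An `es_dataset` of candidate neighbours (non-empty).
#' @param w Non-negative weight vector, one entry per pool covariate.
#' @param spec A [model_spec()].
#' @param floor Underflow floor for the similarity mass.
#' @return A list of class `prediction_result`: `value`, `weight_mass`
#'   (the total similarity mass), `fallback_used`.
#' @export
predict_one <- function(target, pool, w, spec, floor = .mass_floor) {
  stopifnot(inherits(pool, "es_dataset"), inherits(spec, "model_spec"))
  if (pool$n < 1) stop("empty pool", call. = FALSE)
  check_m2_data(pool, spec)
  check_numeric_kinds(pool$schema, spec$distance)
  w <- check_weights(as.numeric(w))
  if (length(w) != pool$m)
    stop("weight vector has length ", length(w), ", expected ", pool$m,
         call. = FALSE)
  target_data <- es_dataset(as.data.frame(target), 0, pool$schema)
  res <- predict_core(covariate_matrix(target_data), covariate_matrix(pool),
                      pool$response, w, spec, floor = floor)
  structure(list(value = res$values[1L], weight_mass = res$mass[1L],
                 fallback_used = res$fallback[1L]),
            class = "prediction_result")
}

#' Similarity predictions for a set of target rows
#'
#' Vectorised form of [predict_one()]: one prediction per row of `targets`,
#' all sharing the same pool.
#'
#' @param targets An `es_dataset` (its response, if any, is ignored) or a
#'   data frame of covariate rows.
#' @param pool An `es_dataset`.
#' @inheritParams predict_one
#' @return A data frame with columns `value`, `weight_mass`,
#'   `fallback_used`.
#' @export
predict_rows <- function(targets, pool, w, spec, floor = .mass_floor) {
  stopifnot(inherits(pool, "es_dataset"), inherits(spec, "model_spec"))
  if (pool$n < 1) stop("empty pool", call. = FALSE)
  check_m2_data(pool, spec)
  check_numeric_kinds(pool$schema, spec$distance)
  w <- check_weights(as.numeric(w))
  if (!inherits(targets, "es_dataset"))
    targets <- es_dataset(as.data.frame(targets),
                          numeric(nrow(as.data.frame(targets))), pool$schema)
  res <- predict_core(covariate_matrix(targets), covariate_matrix(pool),
                      pool$response, w, spec, floor = floor)
  data.frame(value = res$values, weight_mass = res$mass,
             fallback_used = res$fallback)
}

#' Leave-one-out residuals of the similarity model
#'
#' For every observation t, the residual y_t minus the similarity prediction
#' of y_t from all other rows of the same dataset. The sum of their squares
#' is the least-squares objective for the weight estimation.
#'
#' @param data An `es_dataset` with n >= 2.
#' @param w Non-negative weight vector.
#' @param spec A [model_spec()].
#' @return Numeric vector of length n.
#' @export
residuals_loo <- function(data, w, spec) {
  stopifnot(inherits(data, "es_dataset"))
  if (data$n < 2) stop("need n >= 2 for leave-one-out residuals",
                       call. = FALSE)
  check_m2_data(data, spec)
  check_numeric_kinds(data$schema, spec$distance)
  w <- check_weights(as.numeric(w))
  X <- covariate_matrix(data)
  mask <- 1 - diag(data$n)
  res <- predict_core(X, X, data$response, w, spec, mask = mask)
  data$response - res$values
}

#' Sequential one-step-ahead residuals of the similarity model
#'
#' Under the sequential reading of the model, observation t is predicted from
#' rows 1..t-1 only, in the supplied (dataset) row order. Returns the
#' residuals for t = 2..n; the first observation has no predictor pool and is
#' handled by the likelihood through its mean parameter (see [fit_ml()]).
#'
#' @inheritParams residuals_loo
#' @return Numeric vector of length n - 1 (residuals for t = 2..n).
#' @export
residuals_sequential <- function(data, w, spec) {
  stopifnot(inherits(data, "es_dataset"))
  if (data$n < 2) stop("need n >= 2 for sequential residuals", call. = FALSE)
  check_m2_data(data, spec)
  check_numeric_kinds(data$schema, spec$distance)
  w <- check_weights(as.numeric(w))
  X <- covariate_matrix(data)
  n <- data$n
  # pool row i eligible for target t iff i < t
  mask <- outer(seq_len(n), seq_len(n), `<`) * 1
  res <- predict_core(X, X, data$response, w, spec, mask = mask)
  (data$response - res$values)[-1L]
}
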