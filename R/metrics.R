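#' Specify a weighted distance
#'
#' Three weighted covariate distances are available:
#' \describe{
#'   \item{WBD}{weighted binary distance, \eqn{(\sum_l w_l 1[x_l \ne x'_l])^\delta}:
#'     sums the weights of covariates whose values differ, then raises the
#'     sum to the exponent \eqn{\delta}.}
#'   \item{WED}{weighted (squared) Euclidean distance,
#'     \eqn{(\sum_l w_l (x_l - x'_l)^2)^\delta}. The kernel consumes this
#'     squared form directly; no square root is taken.}
#'   \item{WMD}{weighted Minkowski distance of order \eqn{\gamma},
#'     \eqn{(\sum_l w_l |x_l - x'_l|^\gamma)^{1/\gamma}}.}
#' }
#' At `delta = 1` the WBD/WED reduce to the unmodified weighted binary and
#' squared-Euclidean forms. The exponent is applied to the aggregated sum:
#' on 0/1 indicator covariates a per-term exponent would be inert (an
#' indicator to any power is itself), whereas the aggregated placement keeps
#' \eqn{\delta} active and makes WBD and WED coincide on all-binary rows for
#' every \eqn{\delta}. `delta` and `gamma` are scenario constants fixed by
#' configuration, never estimated.
#'
#' @param kind `"wbd"`, `"wed"` or `"wmd"`.
#' @param delta Positive exponent for WBD/WED (default 1).
#' @param gamma Positive Minkowski order for WMD (default 1).
#' @return An object of class `distance_spec`.
#' @examples
#' distance_spec("wed", delta = 2)
#' distance_spec("wmd", gamma = 1 / 4)
#' @export
distance_spec <- function(kind = c("wed", "wbd", "wmd"), delta = 1,
                          gamma = 1) {
  kind <- match.arg(tolower(kind), c("wed", "wbd", "wmd"))
  if (kind == "wmd") {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
        gamma <= 0)
      stop("'gamma' must be a positive number", call. = FALSE)
    delta <- NA_real_
  } else {
    if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
        delta <= 0)
      stop("'delta' must be a positive number", call. = FALSE)
    gamma <- NA_real_
  }
  structure(list(kind = kind, delta = delta, gamma = gamma),
            class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat(toupper(x$kind),
      if (x$kind == "wmd") paste0("(gamma = ", x$gamma, ")")
      else paste0("(delta = ", x$delta, ")"), "\n")
  invisible(x)
}

#' Specify a similarity kernel
#'
#' Maps a non-negative distance d to a similarity in (0, 1]: the exponential
#' inverse `"ex"` gives exp(-d) and the fractional inverse `"fr"` gives
#' 1 / (1 + d). Both equal 1 at d = 0, decrease strictly in d and vanish as
#' d grows.
#'
#' @param kind `"ex"` or `"fr"`.
#' @return An object of class `similarity_spec`.
#' @export
similarity_spec <- function(kind = c("ex", "fr")) {
  kind <- match.arg(tolower(kind), c("ex", "fr"))
  structure(list(kind = kind), class = "similarity_spec")
}

# numeric covariate matrix for distance computation; categorical covariates
# become integer level codes (valid only where equality is compared)
covariate_matrix <- function(data) {
  schema <- data$schema
  X <- matrix(0, nrow = data$n, ncol = data$m,
              dimnames = list(NULL, schema$names))
  for (j in seq_along(schema$names)) {
    nm <- schema$names[j]
    v <- data$covariates[[nm]]
    if (schema$kinds[j] == "categorical") {
      X[, j] <- match(v, schema_levels(schema, nm))
    } else {
      X[, j] <- as.numeric(v)
    }
  }
  X
}

check_numeric_kinds <- function(schema, spec) {
  if (spec$kind %in% c("wed", "wmd") && any(schema$kinds == "categorical"))
    stop(toupper(spec$kind), " requires numeric (ordinal or binary) ",
         "covariates; categorical covariate present: ",
         paste(schema$names[schema$kinds == "categorical"], collapse = ", "),
         call. = FALSE)
}

# Per-covariate pairwise term matrices between the rows of X (nr x m) and
# Xp (np x m), flattened to an (nr*np) x m matrix so that the weighted sum
# for any w is a single matrix-vector product.
pairwise_terms <- function(X, Xp, spec) {
  nr <- nrow(X); np <- nrow(Xp); m <- ncol(X)
  out <- matrix(0, nr * np, m)
  for (l in seq_len(m)) {
    D <- outer(X[, l], Xp[, l], `-`)
    out[, l] <- switch(spec$kind,
      wbd = as.numeric(D != 0),
      wed = as.numeric(D^2),
      wmd = as.numeric(abs(D)^spec$gamma))
  }
  out
}

# distance matrix (nr x np) from precomputed terms and a weight vector
terms_to_distance <- function(terms, w, spec, nr, np) {
  base <- matrix(terms %*% w, nr, np)
  if (spec$kind == "wmd") {
    if (spec$gamma != 1) base <- base^(1 / spec$gamma)
  } else if (spec$delta != 1) {
    base <- base^spec$delta
  }
  base
}

#' Weighted distance between two covariate rows
#'
#' @param x,x_prime Covariate rows: numeric vectors of equal length (0/1 for
#'   binary covariates, level codes or values for others).
#' @param w Non-negative weight vector of the same length.
#' @param spec A [distance_spec()].
#' @return A single non-negative number; 0 when the rows are equal, and
#'   symmetric in its two row arguments.
#' @examples
#' distance(c(0, 0), c(3, 4), c(1, 1), distance_spec("wed"))       # 25
#' distance(c(0, 0), c(3, 4), c(1, 1), distance_spec("wmd", gamma = 2)) # 5
#' @export
distance <- function(x, x_prime, w, spec) {
  stopifnot(inherits(spec, "distance_spec"))
  x <- as.numeric(x); x_prime <- as.numeric(x_prime); w <- as.numeric(w)
  if (length(x) != length(x_prime) || length(x) != length(w))
    stop("x, x_prime and w must have the same length", call. = FALSE)
  check_weights(w)
  if (anyNA(x) || anyNA(x_prime))
    stop("non-numeric or missing covariate values; WED/WMD need numeric ",
         "covariates", call. = FALSE)
  terms <- pairwise_terms(matrix(x, 1), matrix(x_prime, 1), spec)
  drop(terms_to_distance(terms, w, spec, 1L, 1L))
}

check_weights <- function(w) {
  if (anyNA(w) || any(w < 0))
    stop("weights must be non-negative", call. = FALSE)
  invisible(w)
}

#' Similarity of a distance
#'
#' @param d Non-negative finite distance(s).
#' @param spec A [similarity_spec()].
#' @return Similarities in (0, 1], vectorised over `d`.
#' @examples
#' similarity(0, similarity_spec("ex"))      # 1
#' similarity(1, similarity_spec("fr"))      # 0.5
#' similarity(log(2), similarity_spec("ex")) # 0.5
#' @export
similarity <- function(d, spec) {
  stopifnot(inherits(spec, "similarity_spec"))
  if (anyNA(d) || any(!is.finite(d)) || any(d < 0))
    stop("distances must be non-negative and finite", call. = FALSE)
  similarity_kernel(d, spec)
}

# internal kernel: tolerates Inf (maps to similarity 0)
similarity_kernel <- function(d, spec) {
  if (spec$kind == "ex") exp(-d) else 1 / (1 + d)
}
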