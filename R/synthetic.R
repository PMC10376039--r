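#' Default synthetic cell means for the tooth-growth-like generator
#'
#' A 3 x 2 matrix (dose level x supplement) of synthetic mean responses,
#' increasing in dose for both supplements with the orange-juice arm ahead at
#' the lower doses — the qualitative pattern of the real experiment. These
#' are package constants for simulation, not measured values.
#'
#' @return A 3 x 2 numeric matrix with dimnames `dose` (0.5, 1, 2) and
#'   `supp` (0 = VC, 1 = OJ).
#' @export
toothlike_cell_means <- function() {
  matrix(c(8, 17, 26,    # VC (supp = 0)
           13, 22, 26),  # OJ (supp = 1)
         nrow = 3, dimnames = list(dose = c("0.5", "1", "2"),
                                   supp = c("0", "1")))
}

#' Generate a tooth-growth-like factorial dataset
#'
#' A full 3 x 2 factorial (dose x supplement) with equal replication:
#' `reps_per_cell` rows per cell, response = cell mean + Gaussian noise.
#' The default 10 replicates per cell give the 60-observation layout of the
#' real experiment. The generator is a pure function of its configuration:
#' the same seed always yields the same dataset, and the caller's RNG state
#' is untouched.
#'
#' @param cell_means 3 x 2 matrix of mean responses (rows = dose levels 0.5,
#'   1, 2; columns = supplement 0, 1).
#' @param sigma Within-cell noise standard deviation (>= 0).
#' @param reps_per_cell Replicates per cell (>= 1).
#' @param seed Integer seed.
#' @return An `es_dataset` under [tooth_schema()] with
#'   n = 6 * reps_per_cell.
#' @export
generate_toothlike <- function(cell_means = toothlike_cell_means(),
                               sigma = 3, reps_per_cell = 10, seed = 1) {
  if (!is.matrix(cell_means) || !all(dim(cell_means) == c(3, 2)))
    stop("'cell_means' must be a 3 x 2 matrix (dose x supplement)",
         call. = FALSE)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (reps_per_cell < 1) stop("'reps_per_cell' must be >= 1", call. = FALSE)
  doses <- c(0.5, 1, 2)
  grid <- expand.grid(rep = seq_len(reps_per_cell), dose_i = 1:3,
                      supp = c(0, 1))
  mu <- cell_means[cbind(grid$dose_i, grid$supp + 1L)]
  y <- mu + with_seed(seed, stats::rnorm(nrow(grid), 0, sigma))
  es_dataset(data.frame(dose = doses[grid$dose_i], supp = grid$supp), y,
             tooth_schema())
}

#' Generate data from the sequential similarity process
#'
#' Simulates the data-generating process under which the sequential
#' likelihood of [fit_ml()] is exact: the first response is
#' `alpha` + noise, and every later response is the similarity-weighted mean
#' of all preceding responses (under `true_weights` and `spec`) plus
#' Gaussian noise. The sequential form is used because the leave-one-out
#' form of the model defines a simultaneous system with no direct sampling
#' scheme. Covariate rows are supplied, or drawn uniformly from the
#' tooth-growth schema.
#'
#' @param true_weights Non-negative weight vector of the generating model.
#' @param sigma Noise standard deviation (>= 0).
#' @param alpha Mean of the first observation.
#' @param n Number of observations (>= 2).
#' @param spec A [model_spec()] (defaults to M1 / WED delta = 1 / EX).
#' @param seed Integer seed.
#' @param covariates Optional data frame of n covariate rows conforming to
#'   `schema`.
#' @param schema Schema used when drawing covariates (default
#'   [tooth_schema()]).
#' @return An `es_dataset` of length n.
#' @export
generate_similarity_process <- function(true_weights, sigma = 1, alpha = 0,
                                        n = 100,
                                        spec = model_spec(
                                          "M1", distance_spec("wed"),
                                          similarity_spec("ex")),
                                        seed = 1, covariates = NULL,
                                        schema = tooth_schema()) {
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  true_weights <- check_weights(as.numeric(true_weights))
  with_seed(seed, {
    if (is.null(covariates)) {
      covariates <- as.data.frame(lapply(
        stats::setNames(schema$names, schema$names), function(nm) {
          lv <- schema_levels(schema, nm)
          if (is.null(lv)) stop("schema covariate '", nm,
                                "' has no levels to draw from",
                                call. = FALSE)
          sample(lv, n, replace = TRUE)
        }))
    }
    noise <- stats::rnorm(n, 0, sigma)
    blank <- es_dataset(covariates, rep(0, n), schema)
    check_numeric_kinds(schema, spec$distance)
    X <- covariate_matrix(blank)
    y <- numeric(n)
    y[1L] <- alpha + noise[1L]
    for (t in 2:n) {
      pr <- predict_core(X[t, , drop = FALSE], X[seq_len(t - 1L), ,
                                                 drop = FALSE],
                         y[seq_len(t - 1L)], true_weights, spec)
      y[t] <- pr$values[1L] + noise[t]
    }
    es_dataset(covariates, y, schema)
  })
}
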