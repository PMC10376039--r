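#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the absolute
#' sample mean: a dimensionless dispersion measure suited to comparing the
#' variability of estimators living on different scales. Conventions for
#' degenerate inputs: if both the sd and |mean| are below 1e-12 the CV is 0
#' (an estimator that is constant at zero is not variable); if only |mean|
#' is, the CV is +Inf.
#'
#' @param values Numeric vector of length >= 2.
#' @return A non-negative number (possibly `Inf`).
#' @examples
#' coefficient_of_variation(c(2, 4)) # sqrt(2) / 3
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values for a coefficient of variation",
         call. = FALSE)
  s <- stats::sd(values)
  m <- abs(mean(values))
  if (s < 1e-12 && m < 1e-12) return(0)
  if (m < 1e-12) return(Inf)
  s / m
}

#' Mean squared error
#'
#' @param predicted,truth Numeric vectors of equal length >= 1.
#' @return Mean of the squared differences.
#' @export
mean_squared_error <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' differ in length", call. = FALSE)
  if (length(predicted) < 1L) stop("empty vectors", call. = FALSE)
  mean((predicted - truth)^2)
}

new_scenario <- function(model, method = NA_character_,
                         similarity = NULL, distance = NULL) {
  label <- if (model == "LM") "LM"
  else paste(model, toupper(distance$kind),
             if (distance$kind == "wmd") paste0("g", format(distance$gamma))
             else paste0("d", format(distance$delta)),
             toupper(method), toupper(similarity$kind), sep = "_")
  structure(list(model = model, method = method, similarity = similarity,
                 distance = distance, label = label),
            class = "scenario_spec")
}

#' Build the scenario grid of the sensitivity study
#'
#' Crosses the model approaches with estimation methods, similarity kernels
#' and distance settings. The default grid is the full study design: M1 with
#' WBD and WED at delta in {1, 2, 4} and WMD at gamma in
#' {1/4, 1/2, 1, 2, 4}, M2 with WED at delta in {1, 2, 4}, each crossed with
#' {OLS, ML} x {EX, FR} (44 + 12 scenarios), plus the single linear
#' regression benchmark — 57 scenarios in total. Any argument may be
#' restricted to a subset.
#'
#' @param models Subset of `c("M1", "M2", "LM")`.
#' @param methods Subset of `c("ols", "ml")`.
#' @param similarities Subset of `c("ex", "fr")`.
#' @param m1_distances Subset of `c("wbd", "wed", "wmd")` used for M1.
#' @param deltas Exponents for the WBD/WED scenarios.
#' @param gammas Minkowski orders for the WMD scenarios.
#' @return A list of `scenario_spec` objects.
#' @examples
#' length(scenario_grid())                  # 57
#' length(scenario_grid(models = "M2"))     # 12
#' @export
scenario_grid <- function(models = c("M1", "M2", "LM"),
                          methods = c("ols", "ml"),
                          similarities = c("ex", "fr"),
                          m1_distances = c("wbd", "wed", "wmd"),
                          deltas = c(1, 2, 4),
                          gammas = c(1 / 4, 1 / 2, 1, 2, 4)) {
  if (length(models) == 0L) stop("empty model list", call. = FALSE)
  models <- match.arg(toupper(models), c("M1", "M2", "LM"),
                      several.ok = TRUE)
  methods <- match.arg(tolower(methods), c("ols", "ml"), several.ok = TRUE)
  similarities <- match.arg(tolower(similarities), c("ex", "fr"),
                            several.ok = TRUE)
  m1_distances <- match.arg(tolower(m1_distances), c("wbd", "wed", "wmd"),
                            several.ok = TRUE)
  out <- list()
  add <- function(s) out[[length(out) + 1L]] <<- s
  for (model in setdiff(models, "LM")) {
    dspecs <- list()
    if (model == "M1") {
      for (k in setdiff(m1_distances, "wmd"))
        for (d in deltas)
          dspecs[[length(dspecs) + 1L]] <- distance_spec(k, delta = d)
      if ("wmd" %in% m1_distances)
        for (g in gammas)
          dspecs[[length(dspecs) + 1L]] <- distance_spec("wmd", gamma = g)
    } else {
      for (d in deltas)
        dspecs[[length(dspecs) + 1L]] <- distance_spec("wed", delta = d)
    }
    for (dsp in dspecs)
      for (method in methods)
        for (sim in similarities)
          add(new_scenario(model, method, similarity_spec(sim), dsp))
  }
  if ("LM" %in% models) add(new_scenario("LM"))
  out
}

# train split must contain every declared level of every covariate,
# otherwise cell-mean starts / one-hot weights / factor coding are undefined
split_has_all_levels <- function(data, train_idx) {
  schema <- data$schema
  for (j in seq_along(schema$names)) {
    lv <- schema_levels(schema, schema$names[j])
    if (is.null(lv)) next
    if (!all(lv %in% data$covariates[[schema$names[j]]][train_idx]))
      return(FALSE)
  }
  TRUE
}

#' Run one Monte Carlo iteration of the sensitivity protocol
#'
#' Splits the data 70/30 (by default) with the given seed, builds the five
#' cell-mean starts on the training split, fits the scenario's model by
#' multistart (or the closed-form linear benchmark), and scores the fitted
#' model on the test set with the training set as prediction pool. If the
#' training split misses a declared covariate level (so that starts or
#' one-hot weights would be undefined) the split is redrawn with the next
#' seed; the number of redraws is recorded.
#'
#' @param data The full `es_dataset` in original (pre-encoding) form.
#' @param scenario A `scenario_spec` from [scenario_grid()].
#' @param seed Integer seed for the split.
#' @param fraction Training fraction.
#' @param control An [es_control()].
#' @return A list of class `iteration_record`: `seed`, `redraws`, `weights`
#'   (named), `test_mse`, `start_index`, `converged`, `fallback_count`.
#' @export
run_iteration <- function(data, scenario, seed, fraction = 0.7,
                          control = es_control()) {
  stopifnot(inherits(data, "es_dataset"), inherits(scenario, "scenario_spec"))
  redraws <- 0L
  repeat {
    sp <- split_train_test(data$n, fraction, seed + redraws)
    if (split_has_all_levels(data, sp$train)) break
    redraws <- redraws + 1L
    if (redraws > 1000L)
      stop("could not draw a training split containing all levels",
           call. = FALSE)
  }
  train <- subset_rows(data, sp$train)
  test <- subset_rows(data, sp$test)
  if (scenario$model == "LM") {
    fit <- fit_lm(train)
    Xt <- design_matrix(test)
    pred <- drop(Xt %*% fit$coefficients)
    rec <- list(seed = sp$seed, redraws = redraws,
                weights = stats::setNames(fit$coefficients,
                                          fit$design_labels),
                test_mse = mean_squared_error(pred, test$response),
                start_index = NA_integer_, converged = TRUE,
                fallback_count = 0L)
    return(structure(rec, class = "iteration_record"))
  }
  starts <- initial_starts(train, scenario$model)
  if (scenario$model == "M2") {
    train <- encode_m2(train)
    test <- encode_m2(test)
  }
  spec <- model_spec(scenario$model, scenario$distance, scenario$similarity)
  fit <- fit_multistart(train, test, spec, scenario$method, starts, control)
  pr <- predict_rows(test$covariates, train, fit$weights, spec)
  rec <- list(seed = sp$seed, redraws = redraws,
              weights = stats::setNames(fit$weights, train$schema$names),
              test_mse = fit$test_mse, start_index = fit$start_index,
              converged = fit$converged,
              fallback_count = sum(pr$fallback_used))
  structure(rec, class = "iteration_record")
}

#' Monte Carlo sensitivity analysis
#'
#' For each scenario, repeats [run_iteration()] over seeds `base_seed + 1`
#' through `base_seed + R` (the split sequence is therefore shared across
#' scenarios) and summarises, per scenario: the coefficient of variation of
#' every fitted weight across iterations, and the mean and standard
#' deviation of the per-iteration test MSE.
#'
#' @param data The full `es_dataset`.
#' @param scenarios List of `scenario_spec`s, e.g. from [scenario_grid()].
#' @param R Number of Monte Carlo iterations (>= 2).
#' @param base_seed Integer; iteration r uses seed `base_seed + r`.
#' @param fraction Training fraction.
#' @param control An [es_control()].
#' @param verbose Print a progress line per scenario.
#' @return An object of class `sensitivity_result`: list with `summaries`
#'   (one per scenario: `label`, `cv_per_weight`, `mean_mse`, `sd_mse`,
#'   `n_iterations`), `records` (per-scenario lists of iteration records),
#'   and the run settings.
#' @export
run_sensitivity <- function(data, scenarios, R = 30, base_seed = 20230,
                            fraction = 0.7, control = es_control(),
                            verbose = FALSE) {
  if (R < 2) stop("need R >= 2 iterations", call. = FALSE)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  summaries <- vector("list", length(scenarios))
  records <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (verbose) message("scenario ", sc$label, " (", i, "/",
                         length(scenarios), ")")
    recs <- lapply(seq_len(R), function(r)
      run_iteration(data, sc, base_seed + r, fraction, control))
    W <- do.call(rbind, lapply(recs, `[[`, "weights"))
    mses <- vapply(recs, `[[`, numeric(1), "test_mse")
    summaries[[i]] <- list(
      label = sc$label, model = sc$model, method = sc$method,
      cv_per_weight = apply(W, 2L, coefficient_of_variation),
      mean_mse = mean(mses), sd_mse = stats::sd(mses), n_iterations = R)
    records[[i]] <- recs
  }
  names(summaries) <- vapply(scenarios, `[[`, character(1), "label")
  names(records) <- names(summaries)
  structure(list(summaries = summaries, records = records,
                 scenarios = scenarios, R = R, base_seed = base_seed,
                 fraction = fraction),
            class = "sensitivity_result")
}

#' Tidy data frames from a sensitivity run
#'
#' @param result A `sensitivity_result`.
#' @return A list of three data frames: `cv_summary` (scenario, parameter,
#'   cv), `mse_summary` (scenario, mean_mse, sd_mse), and `iterations` (one
#'   row per scenario x iteration with seed, start index, convergence,
#'   fallback count, redraws, test MSE and the fitted weights `w1..w4`).
#' @export
sensitivity_tables <- function(result) {
  stopifnot(inherits(result, "sensitivity_result"))
  cv <- do.call(rbind, lapply(result$summaries, function(s)
    data.frame(scenario = s$label, parameter = names(s$cv_per_weight),
               cv = unname(s$cv_per_weight))))
  mse <- do.call(rbind, lapply(result$summaries, function(s)
    data.frame(scenario = s$label, mean_mse = s$mean_mse,
               sd_mse = s$sd_mse, n_iterations = s$n_iterations)))
  maxw <- max(vapply(result$records,
                     function(rs) length(rs[[1L]]$weights), integer(1)))
  it <- do.call(rbind, unlist(lapply(names(result$records), function(lbl) {
    lapply(seq_along(result$records[[lbl]]), function(r) {
      rec <- result$records[[lbl]][[r]]
      w <- rep(NA_real_, maxw)
      w[seq_along(rec$weights)] <- rec$weights
      cbind(data.frame(scenario = lbl, iteration = r, seed = rec$seed,
                       redraws = rec$redraws,
                       start_index = rec$start_index,
                       converged = rec$converged,
                       fallback_count = rec$fallback_count,
                       test_mse = rec$test_mse),
            stats::setNames(as.data.frame(t(w)), paste0("w", seq_len(maxw))))
    })
  }), recursive = FALSE))
  rownames(cv) <- rownames(mse) <- rownames(it) <- NULL
  list(cv_summary = cv, mse_summary = mse, iterations = it)
}

#' Write the tidy sensitivity outputs
#'
#' Writes `cv_summary.csv`, `mse_summary.csv` and `iterations.csv` into
#' `dir` (created if needed).
#'
#' @param result A `sensitivity_result`.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_sensitivity <- function(result, dir) {
  tabs <- sensitivity_tables(result)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(tabs$cv_summary, file.path(dir, "cv_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tabs$mse_summary, file.path(dir, "mse_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tabs$iterations, file.path(dir, "iterations.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
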