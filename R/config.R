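#' Run the full sensitivity workflow from a configuration
#'
#' Drives load/generate -> scenario grid -> Monte Carlo sensitivity ->
#' tidy outputs from a single configuration, as the command-line interface
#' does. The configuration is a named list (or a path to a YAML file) with
#' blocks:
#' \describe{
#'   \item{data}{either `list(preset = "toothlike", seed =, sigma =,
#'     reps_per_cell =)`, `list(preset = "tooth_growth")` for the real
#'     60-row table, or `list(path =, response =, schema = list(names =,
#'     kinds =, levels =))` for a CSV.}
#'   \item{scenarios}{optional subsets passed to [scenario_grid()]:
#'     `models`, `methods`, `similarities`, `m1_distances`, `deltas`,
#'     `gammas`.}
#'   \item{R, fraction, base_seed}{protocol settings (defaults 30, 0.7,
#'     20230).}
#'   \item{control}{optional optimiser settings for [es_control()].}
#'   \item{out_dir}{output directory.}
#' }
#' Outputs: `cv_summary.csv`, `mse_summary.csv`, `iterations.csv` and
#' `manifest.json` (seeds, settings, package and R versions, config echo).
#' A configuration error raises before anything is written.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the `sensitivity_result` and the written
#'   file paths.
#' @export
run_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  known <- c("data", "scenarios", "R", "fraction", "base_seed", "control",
             "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  R <- config$R %||% 30
  fraction <- config$fraction %||% 0.7
  base_seed <- config$base_seed %||% 20230
  out_dir <- config$out_dir %||% "."
  if (!(is.numeric(fraction) && length(fraction) == 1L && fraction > 0 &&
        fraction < 1))
    stop("'fraction' must be a number strictly between 0 and 1",
         call. = FALSE)
  if (!(is.numeric(R) && R >= 2))
    stop("'R' must be an iteration count >= 2", call. = FALSE)
  ctrl <- do.call(es_control, config$control %||% list())
  data <- config_data(config$data)
  scenarios <- do.call(scenario_grid, config$scenarios %||% list())
  result <- run_sensitivity(data, scenarios, R = R, base_seed = base_seed,
                            fraction = fraction, control = ctrl)
  write_sensitivity(result, out_dir)
  manifest <- list(
    package = "empisim",
    package_version = as.character(utils::packageVersion("empisim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n = data$n, R = R, fraction = fraction, base_seed = base_seed,
    iteration_seeds = base_seed + seq_len(R),
    scenarios = vapply(scenarios, `[[`, character(1), "label"),
    config = config)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(result = result,
                 files = c(file.path(out_dir, c("cv_summary.csv",
                                                "mse_summary.csv",
                                                "iterations.csv")),
                           manifest_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_data <- function(dc) {
  if (is.null(dc)) stop("config lacks a 'data' block", call. = FALSE)
  if (!is.null(dc$preset)) {
    return(switch(dc$preset,
      toothlike = generate_toothlike(
        sigma = dc$sigma %||% 3,
        reps_per_cell = dc$reps_per_cell %||% 10,
        seed = dc$seed %||% 1),
      tooth_growth = tooth_growth(),
      stop("unknown data preset: ", dc$preset, call. = FALSE)))
  }
  if (is.null(dc$path) || is.null(dc$schema) || is.null(dc$response))
    stop("'data' block needs either a preset or path + response + schema",
         call. = FALSE)
  schema <- covariate_schema(dc$schema$names, dc$schema$kinds,
                             dc$schema$levels %||% list())
  load_csv(dc$path, schema, dc$response)
}
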