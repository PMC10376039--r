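#' Construct a similarity dataset
#'
#' Bundles a covariate table, a numeric response vector and a
#' [covariate_schema()] into the validated container used throughout the
#' package.
#'
#' @param covariates A data frame whose columns include every schema
#'   covariate (extra columns are dropped; schema column order is enforced).
#' @param response Numeric response vector, one value per row.
#' @param schema A `covariate_schema`.
#'
#' @return An object of class `es_dataset` with elements `schema`,
#'   `covariates`, `response`, `n` and `m`.
#' @export
es_dataset <- function(covariates, response, schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  covariates <- as.data.frame(covariates)
  missing_cols <- setdiff(schema$names, names(covariates))
  if (length(missing_cols))
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  covariates <- covariates[schema$names]
  response <- as.numeric(response)
  if (nrow(covariates) != length(response))
    stop("covariate rows (", nrow(covariates), ") and response length (",
         length(response), ") differ", call. = FALSE)
  if (anyNA(response))
    stop("response contains missing values", call. = FALSE)
  for (j in seq_along(schema$names)) {
    nm <- schema$names[j]
    lv <- schema_levels(schema, nm)
    if (!is.null(lv)) {
      bad <- which(!(covariates[[nm]] %in% lv))
      if (length(bad))
        stop("covariate '", nm, "' has value outside declared levels at row ",
             bad[1L], " (value: ", covariates[[nm]][bad[1L]], ")",
             call. = FALSE)
    }
    if (schema$kinds[j] %in% c("ordinal", "binary"))
      covariates[[nm]] <- as.numeric(if (is.numeric(covariates[[nm]]))
        covariates[[nm]] else as.character(covariates[[nm]]))
  }
  structure(list(schema = schema, covariates = covariates,
                 response = response, n = length(response),
                 m = length(schema$names)),
            class = "es_dataset")
}

#' @export
print.es_dataset <- function(x, ...) {
  cat("Similarity dataset: n =", x$n, "observations, m =", x$m,
      "covariates\n")
  print(x$schema)
  if (x$n > 0) {
    cat("response: mean", format(mean(x$response), digits = 4),
        "range [", format(min(x$response), digits = 4), ",",
        format(max(x$response), digits = 4), "]\n")
  }
  invisible(x)
}

#' Subset the rows of a dataset
#'
#' @param data An `es_dataset`.
#' @param idx Integer row indices.
#' @return An `es_dataset` with the selected rows, in the order of `idx`.
#' @export
subset_rows <- function(data, idx) {
  stopifnot(inherits(data, "es_dataset"))
  es_dataset(data$covariates[idx, , drop = FALSE], data$response[idx],
             data$schema)
}

#' Read a dataset from CSV
#'
#' The file must have a header containing the response column and every
#' schema covariate. Categorical text values are matched against the declared
#' levels; for the tooth-growth schema the supplement column may hold the
#' labels `VC`/`OJ`, which are recoded 0/1.
#'
#' @param path Path to a comma-separated file (UTF-8, `.` decimal mark).
#' @param schema A `covariate_schema`.
#' @param response_column Name of the response column.
#' @return An `es_dataset`.
#' @export
load_csv <- function(path, schema, response_column) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(response_column, schema$names)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cov <- raw[schema$names]
  for (j in seq_along(schema$names)) {
    nm <- schema$names[j]
    if (schema$kinds[j] == "binary" && is.character(cov[[nm]])) {
      # text labels for a binary covariate: recode in declared label order,
      # VC -> 0, OJ -> 1 for the demo schema
      labs <- unique(c("VC", "OJ", sort(unique(cov[[nm]]))))
      labs <- labs[labs %in% cov[[nm]]]
      cov[[nm]] <- as.numeric(match(cov[[nm]], labs) - 1L)
    }
  }
  es_dataset(cov, raw[[response_column]], schema)
}

#' Write a dataset to CSV
#'
#' Inverse of [load_csv()]: writes the covariate columns plus the response
#' under `response_column`, comma-separated with a header.
#'
#' @param data An `es_dataset`.
#' @param path Output file path.
#' @param response_column Name for the response column.
#' @return `path`, invisibly.
#' @export
save_csv <- function(data, path, response_column = "y") {
  stopifnot(inherits(data, "es_dataset"))
  out <- data$covariates
  out[[response_column]] <- data$response
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The classic guinea-pig tooth-growth data
#'
#' Returns the 60-observation vitamin C tooth-growth experiment bundled with
#' R (`datasets::ToothGrowth`) as an `es_dataset` under [tooth_schema()]:
#' response = tooth length, covariates = dose (mg) and supplement type
#' (VC = 0, OJ = 1).
#'
#' @return An `es_dataset` with n = 60.
#' @export
tooth_growth <- function() {
  tg <- datasets::ToothGrowth
  es_dataset(data.frame(dose = tg$dose,
                        supp = ifelse(tg$supp == "OJ", 1, 0)),
             tg$len, tooth_schema())
}

#' One-hot encode categorical covariates
#'
#' Every covariate with k declared levels (k > 2, or any categorical
#' covariate) is replaced by k 0/1 indicator covariates, one per level, in
#' schema level order; covariates already binary pass through unchanged. The
#' resulting schema is all-binary. This is the "M2" encoding under which a
#' separate weight is attached to each level of a categorical variable.
#'
#' @param data An `es_dataset` with at least one non-binary covariate.
#' @return An all-binary `es_dataset`. If the input is already all-binary it
#'   is returned unchanged.
#' @export
encode_m2 <- function(data) {
  stopifnot(inherits(data, "es_dataset"))
  schema <- data$schema
  if (all(schema$kinds == "binary")) return(data)
  cols <- list(); nms <- character(0); knd <- character(0)
  for (j in seq_along(schema$names)) {
    nm <- schema$names[j]
    if (schema$kinds[j] == "binary") {
      cols[[nm]] <- data$covariates[[nm]]
      nms <- c(nms, nm); knd <- c(knd, "binary")
    } else {
      lv <- schema_levels(schema, nm)
      if (is.null(lv))
        stop("covariate '", nm, "' has no declared levels to encode",
             call. = FALSE)
      for (l in lv) {
        cn <- paste0(nm, "_", format(l, trim = TRUE))
        cols[[cn]] <- as.numeric(data$covariates[[nm]] == l)
        nms <- c(nms, cn); knd <- c(knd, "binary")
      }
    }
  }
  es_dataset(as.data.frame(cols, check.names = FALSE), data$response,
             covariate_schema(nms, knd))
}

#' Random train/test split
#'
#' Draws a simple random sample without replacement of `round(fraction * n)`
#' row indices as the training set; the remainder is the test set. The draw
#' is a pure function of `seed` and leaves the global random-number state
#' untouched.
#'
#' @param n Number of observations (>= 2).
#' @param fraction Training fraction in (0, 1); 0.7 gives the 42/18 split of
#'   the 60-row tooth-growth table.
#' @param seed Integer seed.
#' @return An object of class `split_indices`: list with sorted integer
#'   vectors `train` and `test` and the `seed`.
#' @export
split_train_test <- function(n, fraction, seed) {
  if (n < 2) stop("need n >= 2 to split", call. = FALSE)
  if (!(fraction > 0 && fraction < 1))
    stop("'fraction' must be strictly between 0 and 1", call. = FALSE)
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split leaves an empty train or test set (n = ", n,
         ", fraction = ", fraction, ")", call. = FALSE)
  train <- sort(with_seed(seed, sample.int(n, n_train)))
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' Per-level mean responses
#'
#' For every covariate with declared levels, computes the mean response over
#' the rows where the covariate takes each level. These cell means seed the
#' multistart initial values of the weight estimation.
#'
#' @param data An `es_dataset`.
#' @return A named list, one numeric vector per covariate; the vector is
#'   named by level, in schema level order.
#' @export
cell_means <- function(data) {
  stopifnot(inherits(data, "es_dataset"))
  schema <- data$schema
  out <- list()
  for (j in seq_along(schema$names)) {
    nm <- schema$names[j]
    lv <- schema_levels(schema, nm)
    if (is.null(lv)) next
    means <- vapply(lv, function(l) {
      sel <- data$covariates[[nm]] == l
      if (!any(sel))
        stop("level '", l, "' of covariate '", nm,
             "' is absent from the data; cell mean undefined", call. = FALSE)
      mean(data$response[sel])
    }, numeric(1))
    names(means) <- as.character(lv)
    out[[nm]] <- means
  }
  out
}

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
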