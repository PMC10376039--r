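#' Declare a covariate schema
#'
#' A schema describes the covariate columns of a dataset: their order, their
#' kind, and (for categorical and ordinal covariates) the admissible levels.
#'
#' @param names Character vector of unique, non-empty covariate names, in
#'   column order.
#' @param kinds Character vector, one of `"categorical"`, `"ordinal"` or
#'   `"binary"` per covariate. Ordinal covariates are numeric-valued (e.g. a
#'   dose in mg) and keep their numeric scale in Euclidean/Minkowski
#'   distances; binary covariates take values 0/1; categorical covariates are
#'   compared only by equality.
#' @param levels Named list mapping covariate names to their ordered level
#'   vectors. Required for every categorical covariate (at least 2 levels)
#'   and for ordinal covariates that will be one-hot encoded or used for
#'   cell-mean starts. Binary covariates implicitly have levels `c(0, 1)`.
#'
#' @return An object of class `covariate_schema`.
#' @examples
#' tooth_schema()
#' @export
covariate_schema <- function(names, kinds, levels = list()) {
  if (length(names) == 0L || anyNA(names) || any(!nzchar(names)))
    stop("covariate names must be non-empty", call. = FALSE)
  if (anyDuplicated(names))
    stop("covariate names must be unique", call. = FALSE)
  if (length(kinds) != length(names))
    stop("'kinds' must have one entry per covariate", call. = FALSE)
  kinds <- match.arg(kinds, c("categorical", "ordinal", "binary"),
                     several.ok = TRUE)
  if (!is.list(levels) || (length(levels) && is.null(names(levels))))
    stop("'levels' must be a named list", call. = FALSE)
  for (j in seq_along(names)) {
    lv <- levels[[names[j]]]
    if (kinds[j] == "categorical") {
      if (is.null(lv) || length(lv) < 2L)
        stop("categorical covariate '", names[j],
             "' needs at least 2 declared levels", call. = FALSE)
    }
    if (kinds[j] == "binary" && is.null(lv))
      levels[[names[j]]] <- c(0, 1)
    if (!is.null(levels[[names[j]]]) && anyDuplicated(levels[[names[j]]]))
      stop("duplicated levels for covariate '", names[j], "'", call. = FALSE)
  }
  structure(list(names = names, kinds = kinds,
                 levels = levels[names[names %in% names(levels)]]),
            class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema (", length(x$names), " covariates)\n", sep = "")
  for (j in seq_along(x$names)) {
    lv <- x$levels[[x$names[j]]]
    cat("  ", x$names[j], " <", x$kinds[j], ">",
        if (!is.null(lv)) paste0(": {", paste(lv, collapse = ", "), "}"),
        "\n", sep = "")
  }
  invisible(x)
}

schema_levels <- function(schema, name) {
  lv <- schema$levels[[name]]
  if (is.null(lv) && schema$kinds[match(name, schema$names)] == "binary")
    lv <- c(0, 1)
  lv
}

#' Schema of the guinea-pig tooth-growth table
#'
#' Two covariates: vitamin C dose in mg (ordinal, levels 0.5/1.0/2.0) and
#' food supplement type (binary; ascorbic acid VC = 0, orange juice OJ = 1).
#' The response is tooth (odontoblast) length.
#'
#' @return A `covariate_schema` with covariates `dose` and `supp`.
#' @export
tooth_schema <- function() {
  covariate_schema(names = c("dose", "supp"),
                   kinds = c("ordinal", "binary"),
                   levels = list(dose = c(0.5, 1.0, 2.0), supp = c(0, 1)))
}
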