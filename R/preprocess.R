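#' Drop variables with too many missing values
#'
#' Removes variables whose missing fraction is strictly greater than
#' `max_missing_frac` (default: more than 10% missing). The order of the
#' surviving variables is preserved and the dropped ids are recorded in the
#' `"dropped_ids"` attribute of the result.
#'
#' @param dataset A [cohort_dataset()].
#' @param max_missing_frac Maximum tolerated missing fraction, in `[0, 1)`.
#' @return The filtered `cohort_dataset`.
#' @export
filter_missing <- function(dataset, max_missing_frac = 0.10) {
  max_missing_frac <- check_fraction(max_missing_frac, "max_missing_frac",
                                     0, 1, hi_open = TRUE)
  frac <- colMeans(is.na(dataset$x))
  keep <- frac <= max_missing_frac
  if (!any(keep)) {
    stop("all variables exceed the missing-value threshold; empty dataset",
         call. = FALSE)
  }
  out <- subset_variables(dataset, which(keep))
  attr(out, "dropped_ids") <- variable_ids(dataset)[!keep]
  out
}

#' Impute missing values with the per-variable median
#'
#' Each missing entry is replaced by the median of the variable's observed
#' entries across all samples (both classes pooled, so no label information
#' leaks into the features). Observed entries are unchanged.
#'
#' @param dataset A [cohort_dataset()].
#' @return The dataset with no missing entries.
#' @export
impute_median <- function(dataset) {
  x <- dataset$x
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0L)) {
    stop("variable(s) with no observed values: ",
         paste(variable_ids(dataset)[n_obs == 0L], collapse = ", "),
         "; run filter_missing() first", call. = FALSE)
  }
  for (j in which(colSums(is.na(x)) > 0L)) {
    med <- stats::median(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- med
  }
  dataset$x <- x
  dataset
}

#' Drop variables that are too sparse in either class
#'
#' A variable is kept only if, in each decision class separately, the
#' fraction of non-zero observed entries is at least `min_nonzero_frac`.
#' By default the rule is applied only to variables tagged as RNA-seq-like
#' sources (tags `G`, `J`, `T`), where excess zeros are expected; pass
#' `tags = NULL` to apply it to every variable.
#'
#' @param dataset A [cohort_dataset()].
#' @param min_nonzero_frac Required non-zero fraction per class, in `[0, 1]`.
#' @param tags Source tags the rule applies to, or `NULL` for all variables.
#' @return The filtered `cohort_dataset` with a `"dropped_ids"` attribute.
#' @export
filter_sparse_nonzero <- function(dataset, min_nonzero_frac = 0.5,
                                  tags = c("G", "J", "T")) {
  min_nonzero_frac <- check_fraction(min_nonzero_frac, "min_nonzero_frac", 0, 1)
  targeted <- if (is.null(tags)) rep(TRUE, ncol(dataset$x))
              else dataset$source_tags %in% tags
  keep <- rep(TRUE, ncol(dataset$x))
  for (cls in c(0L, 1L)) {
    xc <- dataset$x[dataset$labels == cls, , drop = FALSE]
    nz <- colSums(xc != 0, na.rm = TRUE)
    obs <- colSums(!is.na(xc))
    frac <- ifelse(obs > 0, nz / obs, 0)
    keep <- keep & (!targeted | frac >= min_nonzero_frac)
  }
  if (!any(keep)) {
    stop("all variables fail the sparsity rule; empty dataset", call. = FALSE)
  }
  out <- subset_variables(dataset, which(keep))
  attr(out, "dropped_ids") <- variable_ids(dataset)[!keep]
  out
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: the missing-value filter, the per-class sparsity rule,
#' and median imputation, so that no missing values reach feature selection.
#'
#' @inheritParams filter_missing
#' @inheritParams filter_sparse_nonzero
#' @return A list with `dataset` (clean [cohort_dataset()]) and `report`
#'   (counts and ids dropped per rule).
#' @export
preprocess_cohort <- function(dataset, max_missing_frac = 0.10,
                              min_nonzero_frac = 0.5, tags = c("G", "J", "T")) {
  d1 <- filter_missing(dataset, max_missing_frac)
  dropped_missing <- attr(d1, "dropped_ids")
  d2 <- filter_sparse_nonzero(d1, min_nonzero_frac, tags)
  dropped_sparse <- attr(d2, "dropped_ids")
  d3 <- impute_median(d2)
  report <- list(
    n_input = ncol(dataset$x),
    n_output = ncol(d3$x),
    dropped_missing = dropped_missing %||% character(0),
    dropped_sparse = dropped_sparse %||% character(0)
  )
  list(dataset = d3, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a preprocessing report as JSON
#' @param report The `report` element of [preprocess_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
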