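#' Cohort dataset container
#'
#' Bundles a samples-by-variables numeric matrix with a binary decision label
#' and per-variable provenance tags. Missing values are stored as `NA` in the
#' matrix. The positive class (label 1) denotes the minority outcome
#' (non-survivor) throughout the package.
#'
#' @param x Numeric matrix, samples in rows, variables in columns. Column
#'   names are the variable identifiers (generated as `V1..Vm` when absent)
#'   and must be unique.
#' @param labels Vector of 0/1 class labels, one per row of `x`; both classes
#'   must be present.
#' @param source_tags Optional character vector, one tag per variable,
#'   recording which data set a variable came from (e.g. `"MA"`, `"G"`,
#'   `"CNV"`). Used by the sparsity filter and by data-set integration.
#' @param sample_ids Optional sample identifiers; defaults to row names or
#'   `S1..Sn`.
#'
#' @return An object of class `cohort_dataset` with elements `x`, `labels`,
#'   `source_tags`, `sample_ids`.
#' @export
cohort_dataset <- function(x, labels, source_tags = NULL, sample_ids = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (samples x variables)", call. = FALSE)
  }
  n <- nrow(x)
  m <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(m))
  if (anyDuplicated(colnames(x))) {
    stop("variable identifiers (column names) must be unique", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("`labels` must have one entry per sample (row)", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("`labels` must be 0/1 with no missing values", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both decision classes must be present", call. = FALSE)
  }
  if (is.null(source_tags)) {
    source_tags <- rep(NA_character_, m)
  } else {
    source_tags <- as.character(source_tags)
    if (length(source_tags) != m) {
      stop("`source_tags` must have one entry per variable", call. = FALSE)
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(x))) rownames(x) else paste0("S", seq_len(n))
  }
  rownames(x) <- sample_ids
  structure(
    list(x = x, labels = labels, source_tags = source_tags,
         sample_ids = sample_ids),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "cohort_dataset: %d samples x %d variables (%d positive / %d negative)\n",
    nrow(x$x), ncol(x$x), sum(x$labels == 1L), sum(x$labels == 0L)))
  miss <- sum(is.na(x$x))
  if (miss > 0) cat(sprintf("  missing entries: %d (%.1f%%)\n",
                            miss, 100 * miss / length(x$x)))
  tags <- unique(x$source_tags[!is.na(x$source_tags)])
  if (length(tags)) cat("  source tags:", paste(tags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$x)

#' Variable identifiers of a cohort
#' @param dataset A [cohort_dataset()].
#' @return Character vector of variable ids.
#' @export
variable_ids <- function(dataset) colnames(dataset$x)

#' Subset a cohort by samples
#' @param dataset A [cohort_dataset()].
#' @param idx Integer or logical index over samples.
#' @return A `cohort_dataset` restricted to the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  cohort_dataset(dataset$x[idx, , drop = FALSE], dataset$labels[idx],
                 source_tags = dataset$source_tags,
                 sample_ids = dataset$sample_ids[idx])
}

#' Subset a cohort by variables
#' @param dataset A [cohort_dataset()].
#' @param ids Character vector of variable ids (or integer index).
#' @return A `cohort_dataset` restricted to the selected variables.
#' @export
subset_variables <- function(dataset, ids) {
  j <- if (is.character(ids)) match(ids, variable_ids(dataset)) else ids
  if (anyNA(j)) {
    stop("unknown variable id(s): ",
         paste(ids[is.na(j)], collapse = ", "), call. = FALSE)
  }
  cohort_dataset(dataset$x[, j, drop = FALSE], dataset$labels,
                 source_tags = dataset$source_tags[j],
                 sample_ids = dataset$sample_ids)
}

#' Write a cohort to tab-separated text
#'
#' Samples in rows; first column `sample_id`, second column `label`, then one
#' column per variable. Missing entries are written as empty fields.
#'
#' @param dataset A [cohort_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  df <- data.frame(sample_id = dataset$sample_ids, label = dataset$labels,
                   dataset$x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  tag_path <- paste0(path, ".tags")
  if (any(!is.na(dataset$source_tags))) {
    utils::write.table(
      data.frame(variable_id = variable_ids(dataset), tag = dataset$source_tags),
      tag_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort from tab-separated text
#'
#' Inverse of [write_cohort()]: expects a `sample_id` column, a `label`
#' column in {0,1}, and numeric variable columns with empty fields for
#' missing values. A sidecar `<path>.tags` file, if present, restores the
#' per-variable source tags.
#'
#' @param path Input file path.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, na.strings = "", check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("cohort file must contain `sample_id` and `label` columns", call. = FALSE)
  }
  vars <- setdiff(names(df), c("sample_id", "label"))
  x <- as.matrix(df[, vars, drop = FALSE])
  storage.mode(x) <- "double"
  tags <- NULL
  tag_path <- paste0(path, ".tags")
  if (file.exists(tag_path)) {
    td <- utils::read.delim(tag_path)
    tags <- td$tag[match(vars, td$variable_id)]
  }
  cohort_dataset(x, df$label, source_tags = tags,
                 sample_ids = as.character(df$sample_id))
}
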