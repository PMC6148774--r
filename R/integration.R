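#' Bind two cohorts measured on the same samples
#'
#' Joins, column-wise, two data sets (e.g. gene expression and copy-number
#' variation) profiled on a common sample cohort. Variable ids are namespaced
#' with the given tags (`"GE.<id>"`, `"CNV.<id>"`), so the same raw id coming
#' from two sources never collides.
#'
#' @param a,b Two [cohort_dataset()]s with identical samples and labels.
#' @param tags Length-2 character vector of namespace tags.
#' @return A joint `cohort_dataset` whose `source_tags` are the namespace
#'   tags.
#' @export
bind_cohorts <- function(a, b, tags = c("GE", "CNV")) {
  if (nrow(a$x) != nrow(b$x) || !all(a$labels == b$labels)) {
    stop("samples mismatch between sources: integration requires the common cohort",
         call. = FALSE)
  }
  xa <- a$x; colnames(xa) <- paste0(tags[1], ".", colnames(a$x))
  xb <- b$x; colnames(xb) <- paste0(tags[2], ".", colnames(b$x))
  cohort_dataset(cbind(xa, xb), a$labels,
                 source_tags = c(rep(tags[1], ncol(xa)), rep(tags[2], ncol(xb))),
                 sample_ids = a$sample_ids)
}

#' Merge feature sets across data sets
#'
#' Takes the `n_base` highest-scoring variables from a gene-expression-like
#' filter result and extends them with *all* variables identified as
#' relevant, by the same method, in a copy-number-like data set. Ids are
#' namespaced by source tag, so the two blocks are disjoint by construction.
#'
#' @param ge_result,cnv_result `filter_result`s from the same method, scored
#'   on the two source data sets separately.
#' @param n_base Size of the gene-expression base set (default 50).
#' @param tags Length-2 namespace tags matching [bind_cohorts()].
#' @return An object of class `merged_feature_set` with `base_ids`,
#'   `added_ids`, `method`.
#' @export
merge_feature_sets <- function(ge_result, cnv_result, n_base = 50L,
                               tags = c("GE", "CNV")) {
  if (ge_result$method != cnv_result$method) {
    stop("both filter results must come from the same method", call. = FALSE)
  }
  n_base <- check_count(n_base, "n_base", min = 1)
  base <- paste0(tags[1], ".", top_n(ge_result, n_base))
  added <- if (length(cnv_result$relevant_ids))
    paste0(tags[2], ".", cnv_result$relevant_ids) else character(0)
  structure(list(base_ids = base, added_ids = added,
                 method = ge_result$method, tags = tags),
            class = "merged_feature_set")
}

#' @export
print.merged_feature_set <- function(x, ...) {
  cat(sprintf("merged_feature_set [%s]: %d base + %d added variables\n",
              x$method, length(x$base_ids), length(x$added_ids)))
  invisible(x)
}

#' Evaluate a merged feature set for synergy between data sets
#'
#' Runs three paired cross-validated evaluations under the *identical* fold
#' plan — the base set alone, the added set alone, and the merged set — and
#' scores synergy as the MCC gain of the merged model over the better of its
#' two components, separately for the out-of-bag and the validation (CV)
#' estimates. The gain over the gene-expression base set alone is also
#' reported. With `stage = 3` the feature sets are re-derived inside every
#' fold: the filter is run per source block on the training part only, the
#' base block contributing its top-`n_base` variables and the added block its
#' full relevant set.
#'
#' @param dataset_joint A joint [bind_cohorts()] dataset containing all
#'   merged ids.
#' @param merged A [merge_feature_sets()] object (stage 2), or the method /
#'   `n_base` template for per-fold re-selection (stage 3).
#' @param plan A [stratified_kfold()] plan.
#' @param stage 2 (fixed feature sets) or 3 (per-fold re-selection).
#' @param alpha,disc,n_permutations,ntree As in the stage runners.
#' @param seed Master seed.
#' @return An object of class `synergy_report`: a data frame with one row
#'   per evaluation mode (`oob`, `cv`) and columns `mcc_base`, `mcc_added`,
#'   `mcc_merged`, `synergy` (vs the component maximum) and
#'   `synergy_vs_base`; plus the three underlying `stage_result`s.
#' @export
synergy_eval <- function(dataset_joint, merged, plan, stage = 2L,
                         alpha = 0.05, disc = discretization(), seed = 1L,
                         ntree = 500L, n_permutations = 20L) {
  if (!inherits(merged, "merged_feature_set")) {
    stop("`merged` must be a merged_feature_set", call. = FALSE)
  }
  if (!stage %in% c(2L, 3L)) stop("`stage` must be 2 or 3", call. = FALSE)
  ids_all <- c(merged$base_ids, merged$added_ids)
  if (!all(ids_all %in% variable_ids(dataset_joint))) {
    stop("joint dataset lacks some merged feature ids", call. = FALSE)
  }
  tags <- merged$tags
  n_base <- length(merged$base_ids)
  seeds <- spawn_seeds(seed, 3L)

  arm_sets <- list(base = merged$base_ids, added = merged$added_ids,
                   merged = ids_all)
  run_arm <- function(ids, s) {
    if (!length(ids)) return(NULL)
    if (stage == 2L) {
      cv <- .run_cv(dataset_joint, plan, function(d, sd) ids,
                    per_fold = FALSE, seed = s, ntree = ntree)
    } else {
      sel_fun <- function(d_train, sd) {
        .select_merged(d_train, merged$method, n_base, tags, ids_kind(ids),
                       alpha, disc, sd, n_permutations)
      }
      cv <- .run_cv(dataset_joint, plan, sel_fun, per_fold = TRUE, seed = s,
                    ntree = ntree)
    }
    .stage_result(stage, merged$method, length(ids), cv$models,
                  cv$feature_lists, cv$predictions, dataset_joint$labels, plan)
  }
  ids_kind <- function(ids) {
    if (identical(ids, merged$base_ids)) "base"
    else if (identical(ids, merged$added_ids)) "added" else "merged"
  }
  arms <- Map(run_arm, arm_sets, as.list(seeds))

  pick <- function(arm, what) {
    if (is.null(arm)) return(NA_real_)
    unname(arm$aggregates[[what]]["mean"])
  }
  report <- do.call(rbind, lapply(c(oob = "mcc_oob", cv = "mcc_validation"),
    function(what) {
      b <- pick(arms$base, what); a <- pick(arms$added, what)
      m <- pick(arms$merged, what)
      data.frame(mcc_base = b, mcc_added = a, mcc_merged = m,
                 synergy = m - max(b, a, na.rm = TRUE),
                 synergy_vs_base = m - b)
    }))
  report <- cbind(mode = c("oob", "cv"), report)
  rownames(report) <- NULL
  structure(list(report = report, method = merged$method, stage = stage,
                 arms = arms), class = "synergy_report")
}

# per-fold re-selection respecting the merging protocol: filter each source
# block of the training data separately, take top-n_base of the base block
# and the full relevant set of the added block
.select_merged <- function(d_train, method, n_base, tags, kind, alpha, disc,
                           seed, n_permutations) {
  seeds <- spawn_seeds(seed, 2L)
  block <- function(tag) {
    j <- which(d_train$source_tags == tag)
    subset_variables(d_train, j)
  }
  base_ids <- if (kind != "added") {
    select_features(block(tags[1]), method, n_base, alpha, disc,
                    seed = seeds[1], n_permutations = n_permutations)$feature_ids
  } else character(0)
  added_ids <- if (kind != "base") {
    res <- switch(method,
      t_test = , t_test_lasso = t_test_filter(block(tags[2]), alpha),
      ig_1d = {
        d2 <- disc; d2$seed <- seeds[2]
        ig1d_filter(block(tags[2]), d2, alpha, n_permutations)
      },
      ig_2d = {
        d2 <- disc; d2$seed <- seeds[2]
        ig2d_filter(block(tags[2]), d2, alpha, n_permutations)
      })
    res$relevant_ids
  } else character(0)
  ids <- c(base_ids, added_ids)
  if (!length(ids)) {
    stop("per-fold selection produced an empty feature set", call. = FALSE)
  }
  ids
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf("synergy_report [%s, stage %d]:\n", x$method, x$stage))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Render aggregate tables from stage and synergy results
#'
#' Collects `stage_result` and `synergy_report` objects into two flat,
#' deterministically ordered tables (by stage, method, N / mode), optionally
#' writing them as CSV plus an aligned human-readable text rendering.
#'
#' @param results A list of `stage_result` and/or `synergy_report` objects.
#' @param dir Optional output directory; when given, writes
#'   `stage_results.csv`, `synergy_results.csv` and `tables.txt`.
#' @return A list of data frames `stages` and `synergies`, invisibly when
#'   `dir` is given.
#' @export
render_tables <- function(results, dir = NULL) {
  if (!length(results)) stop("`results` must be non-empty", call. = FALSE)
  stage_rows <- lapply(Filter(function(r) inherits(r, "stage_result"), results),
    function(s) {
      a <- s$aggregates
      data.frame(stage = s$stage, method = s$method, n_features = s$n_features,
                 n_models = nrow(s$models),
                 mcc_oob_mean = unname(a$mcc_oob["mean"]),
                 mcc_oob_sd = unname(a$mcc_oob["sd"]),
                 mcc_cv_mean = unname(a$mcc_validation["mean"]),
                 mcc_cv_sd = unname(a$mcc_validation["sd"]))
    })
  syn_rows <- lapply(Filter(function(r) inherits(r, "synergy_report"), results),
    function(s) cbind(stage = s$stage, method = s$method, s$report))
  empty_stages <- data.frame(stage = integer(0), method = character(0),
                             n_features = integer(0), n_models = integer(0),
                             mcc_oob_mean = numeric(0), mcc_oob_sd = numeric(0),
                             mcc_cv_mean = numeric(0), mcc_cv_sd = numeric(0))
  empty_syn <- data.frame(stage = integer(0), method = character(0),
                          mode = character(0), mcc_base = numeric(0),
                          mcc_added = numeric(0), mcc_merged = numeric(0),
                          synergy = numeric(0), synergy_vs_base = numeric(0))
  stages <- if (length(stage_rows)) do.call(rbind, stage_rows) else empty_stages
  syn <- if (length(syn_rows)) do.call(rbind, syn_rows) else empty_syn
  if (nrow(stages)) {
    stages <- stages[order(stages$stage, stages$method, stages$n_features), ]
    rownames(stages) <- NULL
  }
  if (nrow(syn)) {
    syn <- syn[order(syn$stage, syn$method, syn$mode), ]
    rownames(syn) <- NULL
  }
  out <- list(stages = stages, synergies = syn)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stages, file.path(dir, "stage_results.csv"),
                     row.names = FALSE)
    utils::write.csv(syn, file.path(dir, "synergy_results.csv"),
                     row.names = FALSE)
    txt <- c("Model quality (MCC) by stage, method and N",
             utils::capture.output(print(stages, row.names = FALSE)),
             "", "Synergy between data sets",
             utils::capture.output(print(syn, row.names = FALSE)))
    writeLines(txt, file.path(dir, "tables.txt"))
    return(invisible(out))
  }
  out
}
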