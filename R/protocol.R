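#' Repeated stratified k-fold cross-validation plan
#'
#' Both classes are split separately into `k` near-equal parts and then
#' merged, so every fold preserves the minority/majority proportion (per-fold
#' class counts differ by at most one). Each repeat is an independent
#' shuffle.
#'
#' @param labels 0/1 class labels.
#' @param k Number of folds, at least 2.
#' @param repeats Number of independent cross-validation repeats.
#' @param seed Integer seed.
#' @return An object of class `cv_plan` with `k`, `repeats`, `seed`, and
#'   `assignment`: a list (per repeat) of lists (per fold) of validation
#'   sample indices.
#' @export
stratified_kfold <- function(labels, k = 5L, repeats = 100L, seed = 1L) {
  labels <- as.integer(labels)
  k <- check_count(k, "k", min = 2)
  repeats <- check_count(repeats, "repeats", min = 1)
  n_min <- min(table(factor(labels, levels = c(0L, 1L))))
  if (n_min < k) {
    stop(sprintf("minority class has %d samples, fewer than k = %d folds; the training set would not contain a sufficient number of objects",
                 n_min, k), call. = FALSE)
  }
  assignment <- with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold_of <- integer(length(labels))
      for (cls in c(0L, 1L)) {
        idx <- which(labels == cls)
        n <- length(idx)
        sizes <- rep(n %/% k, k)
        extra <- n %% k
        if (extra > 0) {
          lucky <- sample.int(k, extra)
          sizes[lucky] <- sizes[lucky] + 1L
        }
        fold_of[idx] <- sample(rep.int(seq_len(k), sizes))
      }
      lapply(seq_len(k), function(f) sort(which(fold_of == f)))
    })
  })
  structure(list(k = k, repeats = repeats, seed = seed,
                 n_samples = length(labels), assignment = assignment),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d-fold x %d repeats over %d samples (%d validation sets)\n",
              x$k, x$repeats, x$n_samples, x$k * x$repeats))
  invisible(x)
}

# assemble a stage_result from per-model rows
.stage_result <- function(stage, method, n_features, models, feature_lists,
                          predictions, labels, plan = NULL) {
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  structure(list(
    stage = stage, method = method, n_features = n_features,
    models = models, feature_lists = feature_lists,
    predictions = predictions, labels = labels, plan = plan,
    aggregates = list(mcc_oob = agg(models$mcc_oob),
                      mcc_train = agg(models$mcc_train),
                      mcc_validation = agg(models$mcc_validation))
  ), class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("stage_result [stage %d, %s, N = %d]: %d model(s)\n",
              x$stage, x$method, x$n_features, nrow(x$models)))
  cat(sprintf("  mean MCC: OOB %.3f, train %.3f, validation %s\n",
              a$mcc_oob["mean"], a$mcc_train["mean"],
              if (is.nan(a$mcc_validation["mean"])) "-" else
                sprintf("%.3f", a$mcc_validation["mean"])))
  invisible(x)
}

#' Stage 1: minimum error, maximum bias
#'
#' All available data is used both for feature selection and for model
#' building; only the out-of-bag (and training-set) MCC is reported. This is
#' the most optimistic estimate of model quality.
#'
#' @param dataset A preprocessed [cohort_dataset()].
#' @param method Filter method (see [select_features()]).
#' @param n_features Feature subset size.
#' @param alpha,disc,n_permutations Passed to [select_features()].
#' @param seed Master seed.
#' @param ntree Trees per forest.
#' @return A `stage_result` with exactly one model.
#' @export
run_stage1 <- function(dataset, method, n_features, alpha = 0.05,
                       disc = discretization(), seed = 1L, ntree = 500L,
                       n_permutations = 20L) {
  seeds <- spawn_seeds(seed, 2L)
  sel <- select_features(dataset, method, n_features, alpha, disc,
                         seed = seeds[1], n_permutations = n_permutations)
  model <- train_rf(dataset, sel$feature_ids, seed = seeds[2], ntree = ntree)
  models <- data.frame(repeat_ = 1L, fold = NA_integer_,
                       mcc_oob = model$evaluation$mcc_oob,
                       mcc_train = model$evaluation$mcc_train,
                       mcc_validation = NA_real_, seed = seeds[2])
  .stage_result(1L, method, n_features, models,
                feature_lists = list(sel$feature_ids),
                predictions = NULL, labels = dataset$labels)
}

# shared cross-validation engine for stages 2 and 3 and for synergy
# evaluation. `select_fun(train_dataset, seed)` returns feature ids; it is
# called once globally when `per_fold = FALSE`, else once per fold on the
# training part only (the validation part never reaches the filter).
.run_cv <- function(dataset, plan, select_fun, per_fold, seed, ntree) {
  R <- plan$repeats; K <- plan$k
  if (plan$n_samples != nrow(dataset$x)) {
    stop("cv_plan does not cover this dataset", call. = FALSE)
  }
  all_seeds <- spawn_seeds(seed, 2L * R * K + 1L)
  seeds <- matrix(all_seeds[-1L], nrow = 2L)
  sel_global <- if (!per_fold) select_fun(dataset, all_seeds[1L])
  rows <- vector("list", R * K)
  feats <- vector("list", R * K)
  preds <- vector("list", R * K)
  i <- 0L
  for (r in seq_len(R)) {
    for (f in seq_len(K)) {
      i <- i + 1L
      val_idx <- plan$assignment[[r]][[f]]
      train_idx <- setdiff(seq_len(plan$n_samples), val_idx)
      d_train <- subset_samples(dataset, train_idx)
      ids <- if (per_fold) select_fun(d_train, seeds[1, i]) else sel_global
      model <- train_rf(d_train, ids, seed = seeds[2, i], ntree = ntree)
      ev <- predict_eval(model, subset_samples(dataset, val_idx))
      rows[[i]] <- data.frame(repeat_ = r, fold = f,
                              mcc_oob = model$evaluation$mcc_oob,
                              mcc_train = model$evaluation$mcc_train,
                              mcc_validation = ev$mcc, seed = seeds[2, i])
      feats[[i]] <- ids
      preds[[i]] <- data.frame(sample = val_idx, predicted = ev$predicted,
                               repeat_ = r, fold = f)
    }
  }
  list(models = do.call(rbind, rows), feature_lists = feats,
       predictions = preds)
}

#' Stage 2: intermediate bias and error
#'
#' Feature selection is performed once on all available data; the models are
#' then built and evaluated within repeated stratified k-fold
#' cross-validation (train on k-1 parts, validate on the held-out part),
#' recording OOB, training-set and validation-set MCC for each of the
#' `repeats * k` models.
#'
#' @inheritParams run_stage1
#' @param plan A [stratified_kfold()] plan covering the dataset.
#' @return A `stage_result` with `repeats * k` models.
#' @export
run_stage2 <- function(dataset, method, n_features, plan, alpha = 0.05,
                       disc = discretization(), seed = 1L, ntree = 500L,
                       n_permutations = 20L) {
  sel_fun <- function(d, s) {
    select_features(d, method, n_features, alpha, disc, seed = s,
                    n_permutations = n_permutations)$feature_ids
  }
  cv <- .run_cv(dataset, plan, sel_fun, per_fold = FALSE, seed = seed,
                ntree = ntree)
  .stage_result(2L, method, n_features, cv$models, cv$feature_lists,
                cv$predictions, dataset$labels, plan)
}

#' Stage 3: minimum bias, maximum error
#'
#' The entire modelling procedure, including feature selection, is repeated
#' inside every cross-validation fold: the filter sees only the k-1 training
#' parts, so the validation samples never influence the selected features.
#' This is the honest (conservative) estimate of performance on new
#' subjects. When a fold's filter finds no relevant variables, the
#' best-ranked `n_features` are used with a warning.
#'
#' @inheritParams run_stage2
#' @return A `stage_result` with `repeats * k` models and per-fold feature
#'   lists.
#' @export
run_stage3 <- function(dataset, method, n_features, plan, alpha = 0.05,
                       disc = discretization(), seed = 1L, ntree = 500L,
                       n_permutations = 20L) {
  sel_fun <- function(d, s) {
    select_features(d, method, n_features, alpha, disc, seed = s,
                    n_permutations = n_permutations)$feature_ids
  }
  cv <- .run_cv(dataset, plan, sel_fun, per_fold = TRUE, seed = seed,
                ntree = ntree)
  .stage_result(3L, method, n_features, cv$models, cv$feature_lists,
                cv$predictions, dataset$labels, plan)
}

#' Decompose the optimism bias across the three stages
#'
#' Three effects separate the optimistic stage-1 estimate from the honest
#' stage-3 one: the training-set shrinkage in cross-validation
#' (`delta_train_size = OOB1 - OOB2`), the systematic difference between
#' out-of-bag and external validation estimates
#' (`delta_oob_vs_cv = CV2 - OOB2`), and the feature-selection overfitting
#' visible as inflation of the within-fold OOB estimate
#' (`delta_selection = OOB3 - OOB2`). All terms are means over models.
#'
#' @param s1,s2,s3 `stage_result`s for stages 1-3 with matching method and
#'   `n_features`.
#' @return Named list of the three deltas.
#' @export
bias_decomposition <- function(s1, s2, s3) {
  stages <- list(s1, s2, s3)
  if (!all(vapply(stages, function(s) s$method, "") == s1$method) ||
      !all(vapply(stages, function(s) as.numeric(s$n_features), 0) == s1$n_features) ||
      s1$stage != 1L || s2$stage != 2L || s3$stage != 3L) {
    stop("stage results must share method and n_features and be stages 1, 2, 3",
         call. = FALSE)
  }
  oob1 <- s1$aggregates$mcc_oob["mean"]
  oob2 <- s2$aggregates$mcc_oob["mean"]
  cv2 <- s2$aggregates$mcc_validation["mean"]
  oob3 <- s3$aggregates$mcc_oob["mean"]
  list(delta_train_size = unname(oob1 - oob2),
       delta_oob_vs_cv = unname(cv2 - oob2),
       delta_selection = unname(oob3 - oob2))
}

#' Ensemble-of-forests classifier from cross-validation models
#'
#' Pools, for every sample, the validation-set predictions of exactly those
#' cross-validation models that held the sample out (one per repeat). The
#' consensus class is the majority vote, ties going to the cohort majority
#' class; the agreement fraction is the share of the modal class. The
#' ensemble MCC compares the consensus predictions with the truth.
#'
#' @param stage_result A `stage_result` from [run_stage3()] (or
#'   [run_stage2()]) with stored per-model validation predictions.
#' @return An object of class `ensemble_result`: per-sample data frame
#'   (`sample`, `truth`, `votes_total`, `votes_pos`, `votes_neg`,
#'   `consensus`, `agreement`) and the consensus `mcc`.
#' @export
build_ensemble <- function(stage_result) {
  if (is.null(stage_result$predictions)) {
    stop("stage result has no stored validation predictions", call. = FALSE)
  }
  all_pred <- do.call(rbind, stage_result$predictions)
  labels <- stage_result$labels
  n <- length(labels)
  votes_pos <- tabulate(all_pred$sample[all_pred$predicted == 1L], nbins = n)
  votes_total <- tabulate(all_pred$sample, nbins = n)
  votes_neg <- votes_total - votes_pos
  tie_class <- if (mean(labels) > 0.5) 1L else 0L
  consensus <- ifelse(votes_pos > votes_neg, 1L,
                      ifelse(votes_pos < votes_neg, 0L, tie_class))
  agreement <- pmax(votes_pos, votes_neg) / votes_total
  samples <- data.frame(sample = seq_len(n), truth = labels,
                        votes_total = votes_total, votes_pos = votes_pos,
                        votes_neg = votes_neg, consensus = consensus,
                        agreement = agreement)
  structure(list(samples = samples,
                 mcc = mcc(confusion_matrix(labels, consensus))),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d samples, %d votes each; consensus MCC = %.3f\n",
              nrow(x$samples), x$samples$votes_total[1], x$mcc))
  invisible(x)
}

#' Partition samples by prediction stability
#'
#' Splits the cohort into samples that are consistently correctly classified
#' (correct consensus with agreement at or above the threshold), consistently
#' misclassified (wrong consensus with agreement at or above the threshold),
#' and unstable samples (agreement below the threshold). The consistently
#' wrong set flags subjects whose recorded outcome contradicts their
#' molecular profile under essentially every model.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param threshold Agreement fraction separating stable from unstable.
#' @return A list of three integer vectors of sample indices:
#'   `consistently_correct`, `unstable`, `consistently_wrong`.
#' @export
classify_agreement <- function(ensemble, threshold = 0.9) {
  threshold <- check_fraction(threshold, "threshold", 0, 1)
  s <- ensemble$samples
  stable <- s$agreement >= threshold
  correct <- s$consensus == s$truth
  list(consistently_correct = s$sample[stable & correct],
       unstable = s$sample[!stable],
       consistently_wrong = s$sample[stable & !correct])
}

#' Correlation between OOB and validation MCC across models
#'
#' Pearson correlation between the per-model out-of-bag and validation-set
#' MCC estimates of a cross-validated stage. On small cohorts with a shared
#' pool of hard-to-classify samples this correlation is typically negative:
#' when the hard samples land in the training part the OOB estimate drops
#' and the validation estimate rises, and vice versa.
#'
#' @param stage_result A `stage_result` with at least 3 models and validation
#'   MCC values.
#' @return Pearson correlation coefficient, or `NaN` (with a warning) when
#'   either series has zero variance.
#' @export
oob_cv_correlation <- function(stage_result) {
  m <- stage_result$models
  if (nrow(m) < 3L) stop("need at least 3 models", call. = FALSE)
  if (anyNA(m$mcc_validation)) {
    stop("stage result has no validation MCC values", call. = FALSE)
  }
  if (stats::sd(m$mcc_oob) == 0 || stats::sd(m$mcc_validation) == 0) {
    warning("zero variance in MCC series; correlation undefined", call. = FALSE)
    return(NaN)
  }
  stats::cor(m$mcc_oob, m$mcc_validation)
}
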