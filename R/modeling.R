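#' Confusion matrix for binary predictions
#'
#' The positive class (1) is the non-survivor / minority outcome.
#'
#' @param truth 0/1 vector of true classes.
#' @param predicted 0/1 vector of predicted classes.
#' @return An object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted) || !length(truth)) {
    stop("`truth` and `predicted` must be non-empty and of equal length",
         call. = FALSE)
  }
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fp = sum(truth == 0L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, the
#' geometric mean of informedness and markedness; treats both classes with
#' equal weight, which makes it the metric of choice for strongly unbalanced
#' cohorts. If any factor of the denominator is zero the value is 0 by
#' convention.
#'
#' @param cm A [confusion_matrix()], or a named list/vector with `tp`, `fp`,
#'   `tn`, `fn`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm[["tp"]]); fp <- as.numeric(cm[["fp"]])
  tn <- as.numeric(cm[["tn"]]); fn <- as.numeric(cm[["fn"]])
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn == 0) {
    stop("confusion matrix must have non-negative counts and a positive total",
         call. = FALSE)
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# majority vote from a matrix of class-vote fractions (columns "0"/"1");
# ties go to the training-set majority class
.vote_class <- function(votes, tie_class) {
  v1 <- votes[, "1"]; v0 <- votes[, "0"]
  out <- ifelse(v1 > v0, 1L, ifelse(v1 < v0, 0L, tie_class))
  # a sample never out-of-bag has NaN vote fractions; fall back to majority
  out[is.na(out)] <- tie_class
  out
}

#' Train a Random Forest and evaluate it out-of-bag
#'
#' Fits a Random Forest (bootstrap sampling, random feature subsetting at
#' splits; `ntree` trees, `floor(sqrt(p))` candidate variables per split) on
#' the selected features. Each sample's out-of-bag (OOB) class is the
#' majority vote of the trees whose bootstrap sample excluded it, giving a
#' near-independent error estimate without a holdout; vote ties are broken
#' toward the training-set majority class.
#'
#' @param dataset A complete [cohort_dataset()] (training data; both classes
#'   present).
#' @param feature_ids Non-empty character vector of variables to use.
#' @param seed Integer seed; fixed seed gives identical forests.
#' @param ntree Number of trees (default 500).
#' @return An object of class `rf_model`: the fitted forest, the feature ids,
#'   and `evaluation` with `mcc_oob` and `mcc_train`.
#' @export
train_rf <- function(dataset, feature_ids, seed = 1L, ntree = 500L) {
  if (!length(feature_ids)) stop("`feature_ids` must be non-empty", call. = FALSE)
  dsub <- subset_variables(dataset, feature_ids)
  .check_complete(dsub)
  y <- factor(dsub$labels, levels = c(0L, 1L))
  if (any(table(y) == 0L)) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x <- as.data.frame(dsub$x)
  tie_class <- if (mean(dsub$labels) > 0.5) 1L else 0L
  rf <- with_seed(seed, {
    randomForest::randomForest(x, y, ntree = ntree,
                               mtry = max(1L, floor(sqrt(ncol(x)))))
  })
  oob_pred <- .vote_class(rf$votes, tie_class)
  train_votes <- stats::predict(rf, x, type = "vote", norm.votes = TRUE)
  train_pred <- .vote_class(train_votes, tie_class)
  structure(list(
    rf = rf, feature_ids = feature_ids, seed = seed, tie_class = tie_class,
    evaluation = list(mcc_oob = mcc(confusion_matrix(dsub$labels, oob_pred)),
                      mcc_train = mcc(confusion_matrix(dsub$labels, train_pred)))
  ), class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("rf_model: %d features, %d trees; OOB MCC = %.3f\n",
              length(x$feature_ids), x$rf$ntree, x$evaluation$mcc_oob))
  invisible(x)
}

#' Predict on a holdout set and evaluate with MCC
#'
#' @param model An [train_rf()] model.
#' @param holdout A [cohort_dataset()] containing the model's features.
#' @return A list with `predicted` (0/1 vector), `confusion`
#'   (a [confusion_matrix()]) and `mcc`.
#' @export
predict_eval <- function(model, holdout) {
  if (!inherits(model, "rf_model")) stop("`model` must be an rf_model", call. = FALSE)
  missing <- setdiff(model$feature_ids, colnames(holdout$x))
  if (length(missing)) {
    stop("holdout lacks model features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(holdout$x)) stop("holdout is empty", call. = FALSE)
  x <- as.data.frame(holdout$x[, model$feature_ids, drop = FALSE])
  votes <- stats::predict(model$rf, x, type = "vote", norm.votes = TRUE)
  pred <- .vote_class(votes, model$tie_class)
  cm <- confusion_matrix(holdout$labels, pred)
  list(predicted = pred, confusion = cm, mcc = mcc(cm))
}
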