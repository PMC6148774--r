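#' Welch two-sample t statistic
#'
#' Test of equality of class means with unequal variances: the statistic is
#' `t = (mean_d - mean_s) / sqrt(V_d/n_d + V_s/n_s)` where subscript `d`
#' denotes the non-survivor (positive) class and `s` the survivor class. The
#' two-sided p-value uses the Welch--Satterthwaite degrees of freedom.
#'
#' @param x_d Numeric values of the positive (non-survivor) class.
#' @param x_s Numeric values of the negative (survivor) class.
#' @return A list with elements `t` and `p_raw`.
#' @export
welch_t <- function(x_d, x_s) {
  if (length(x_d) < 2L || length(x_s) < 2L) {
    stop("each class needs at least 2 observations", call. = FALSE)
  }
  n_d <- length(x_d); n_s <- length(x_s)
  v_d <- stats::var(x_d); v_s <- stats::var(x_s)
  num <- mean(x_d) - mean(x_s)
  se2 <- v_d / n_d + v_s / n_s
  if (se2 == 0) {
    if (num == 0) return(list(t = 0, p_raw = 1))
    stop("degenerate variances: both classes constant with unequal means",
         call. = FALSE)
  }
  t <- num / sqrt(se2)
  df <- se2^2 / ((v_d / n_d)^2 / (n_d - 1) + (v_s / n_s)^2 / (n_s - 1))
  list(t = t, p_raw = 2 * stats::pt(-abs(t), df))
}

#' Hochberg step-up adjustment of p-values
#'
#' Family-wise error-rate control by the Hochberg step-up procedure; the
#' adjusted values are returned in the input order and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
hochberg_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "hochberg")
}

#' Plug-in Shannon entropy in bits
#'
#' @param counts Non-negative contingency counts (vector or array) with a
#'   positive total; `0 * log(0)` contributes zero.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("counts must have a positive total", call. = FALSE)
  sum(plogp_bits(counts, total))
}

# entropy of the joint distribution of a list of discrete vectors
.joint_entropy <- function(vars) {
  if (!length(vars)) return(0)
  f <- interaction(as.data.frame(vars), drop = TRUE)
  shannon_entropy(tabulate(f))
}

#' Conditional information gain from empirical counts
#'
#' Conditional mutual information of the label `y` and variable `x` given a
#' conditioning set `s`, computed exactly from the four-entropy identity on
#' the empirical joint counts:
#' `IG(Y; x | S) = H(x, S) - H(Y, x, S) - [H(S) - H(Y, S)]`.
#' With an empty `s` this reduces to the mutual information `IG(Y; x)`.
#'
#' @param y Discrete label vector.
#' @param x Discrete variable, same length.
#' @param s Conditioning variables: `NULL` (empty set), a vector, or a
#'   matrix/data.frame/list of vectors of the same length.
#' @return Information gain in bits (non-negative).
#' @export
conditional_ig <- function(y, x, s = NULL) {
  if (length(y) != length(x)) stop("`y` and `x` must have equal length", call. = FALSE)
  svars <- if (is.null(s)) list()
           else if (is.list(s) && !is.data.frame(s)) s
           else if (is.matrix(s) || is.data.frame(s)) as.list(as.data.frame(s))
           else list(s)
  if (length(svars) && any(lengths(svars) != length(y))) {
    stop("conditioning variables must match the length of `y`", call. = FALSE)
  }
  v <- .joint_entropy(c(list(x), svars)) -
       .joint_entropy(c(list(y, x), svars)) -
       (.joint_entropy(svars) - .joint_entropy(c(list(y), svars)))
  max(v, 0)
}

#' Discretization settings for the information-gain filters
#'
#' Continuous variables are discretized by equal-frequency binning into
#' `n_bins` bins, repeated `n_random_splits` times with randomized boundary
#' jitter (and random tie-breaking), and the information-gain statistic is
#' averaged over the repeats.
#'
#' @param n_bins Number of bins, at least 2.
#' @param n_random_splits Number of repeated randomized discretizations.
#' @param seed Integer seed for the discretization (and permutation) stream.
#' @return An object of class `discretization`.
#' @export
discretization <- function(n_bins = 2L, n_random_splits = 30L, seed = 1L) {
  structure(list(n_bins = check_count(n_bins, "n_bins", min = 2),
                 n_random_splits = check_count(n_random_splits,
                                               "n_random_splits", min = 1),
                 seed = check_count(seed, "seed", min = 0)),
            class = "discretization")
}

# one randomized equal-frequency discretization of a numeric matrix;
# consumes RNG (boundary jitter + random tie-breaking)
.disc_split <- function(x, n_bins) {
  n <- nrow(x)
  probs <- sort((seq_len(n_bins - 1L) +
                 stats::runif(n_bins - 1L, -0.3, 0.3)) / n_bins)
  bins <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j], ties.method = "random")
    findInterval((r - 0.5) / n, probs) + 1L
  }, integer(n))
  dim(bins) <- c(n, ncol(x))
  bins
}

# univariate IG(Y; x) for every variable and every label variant (columns of
# Ymat, 0/1 indicators); returns an m x V matrix
.ig1d_split <- function(bins, Ymat, n_bins) {
  n <- nrow(bins)
  m <- ncol(bins)
  cy <- colSums(Ymat)
  Hy <- plogp_bits(cy, n) + plogp_bits(n - cy, n)
  Hx <- numeric(m)
  Hxy <- matrix(0, m, ncol(Ymat))
  for (b in seq_len(n_bins)) {
    Ib <- (bins == b) * 1
    cb <- colSums(Ib)
    Hx <- Hx + plogp_bits(cb, n)
    c1 <- crossprod(Ib, Ymat)
    Hxy <- Hxy + plogp_bits(c1, n) + plogp_bits(cb - c1, n)
  }
  pmax(sweep(-Hxy, 1, Hx, "+") + rep(Hy, each = m), 0)
}

# pairwise conditional IG(Y; x_i | x_j) matrices, one per label variant;
# returns a list of m x m matrices with NA diagonal
.ig2d_split <- function(bins, Ymat, n_bins) {
  n <- nrow(bins)
  m <- ncol(bins)
  V <- ncol(Ymat)
  I <- lapply(seq_len(n_bins), function(b) (bins == b) * 1)
  Nab <- vector("list", n_bins * n_bins)
  Hxx <- matrix(0, m, m)
  Hj <- numeric(m)
  for (a in seq_len(n_bins)) {
    Hj <- Hj + plogp_bits(colSums(I[[a]]), n)
    for (b in seq_len(n_bins)) {
      N <- crossprod(I[[a]], I[[b]])
      Nab[[(a - 1L) * n_bins + b]] <- N
      Hxx <- Hxx + plogp_bits(N, n)
    }
  }
  out <- vector("list", V)
  for (v in seq_len(V)) {
    yv <- Ymat[, v]
    Hyxx <- matrix(0, m, m)
    Hyj <- numeric(m)
    for (a in seq_len(n_bins)) {
      Iay <- I[[a]] * yv
      cb1 <- colSums(Iay)
      Hyj <- Hyj + plogp_bits(cb1, n) + plogp_bits(colSums(I[[a]]) - cb1, n)
      for (b in seq_len(n_bins)) {
        N1 <- crossprod(Iay, I[[b]])
        N <- Nab[[(a - 1L) * n_bins + b]]
        Hyxx <- Hyxx + plogp_bits(N1, n) + plogp_bits(N - N1, n)
      }
    }
    M <- Hxx - Hyxx
    M <- sweep(M, 2, Hj, "-")
    M <- sweep(M, 2, Hyj, "+")
    M <- pmax(M, 0)
    diag(M) <- NA_real_
    out[[v]] <- M
  }
  out
}

# assemble a filter result: adjusted p-values, ranks, relevant set
.filter_result <- function(method, ids, statistic, p_raw, alpha, binning = NULL) {
  p_adjusted <- hochberg_adjust(p_raw)
  o <- order(p_adjusted, -abs(statistic), ids)
  rk <- integer(length(ids))
  rk[o] <- seq_along(ids)
  scores <- data.frame(variable_id = ids, statistic = statistic,
                       p_raw = p_raw, p_adjusted = p_adjusted, rank = rk,
                       stringsAsFactors = FALSE)
  structure(list(method = method, scores = scores,
                 relevant_ids = ids[o][p_adjusted[o] <= alpha],
                 alpha = alpha, binning = binning),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result [%s]: %d variables scored, %d relevant at alpha = %g\n",
              x$method, nrow(x$scores), length(x$relevant_ids), x$alpha))
  invisible(x)
}

.check_complete <- function(dataset) {
  if (anyNA(dataset$x)) {
    stop("dataset contains missing values; run preprocessing first", call. = FALSE)
  }
}

#' Welch t-test filter with Hochberg correction
#'
#' Scores every variable by the Welch t statistic between the two decision
#' classes, adjusts the two-sided p-values by the Hochberg step-up rule, and
#' declares relevant the variables with adjusted p at or below `alpha`.
#'
#' @param dataset A complete (no missing values) [cohort_dataset()].
#' @param alpha Significance level applied after correction.
#' @return A `filter_result` with method `"t_test"`.
#' @export
t_test_filter <- function(dataset, alpha = 0.05) {
  .check_complete(dataset)
  y <- dataset$labels
  xd <- dataset$x[y == 1L, , drop = FALSE]
  xs <- dataset$x[y == 0L, , drop = FALSE]
  if (nrow(xd) < 2L || nrow(xs) < 2L) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  n_d <- nrow(xd); n_s <- nrow(xs)
  m_d <- colMeans(xd); m_s <- colMeans(xs)
  v_d <- colSums(sweep(xd, 2, m_d)^2) / (n_d - 1)
  v_s <- colSums(sweep(xs, 2, m_s)^2) / (n_s - 1)
  se2 <- v_d / n_d + v_s / n_s
  if (any(se2 == 0 & m_d != m_s)) {
    stop("degenerate variances: constant variable with unequal class means",
         call. = FALSE)
  }
  t <- ifelse(se2 == 0, 0, (m_d - m_s) / sqrt(se2))
  df <- ifelse(se2 == 0, n_d + n_s - 2,
               se2^2 / ((v_d / n_d)^2 / (n_d - 1) + (v_s / n_s)^2 / (n_s - 1)))
  p <- ifelse(se2 == 0, 1, 2 * stats::pt(-abs(t), df))
  .filter_result("t_test", variable_ids(dataset), unname(t), unname(p), alpha)
}

#' Extreme-value significance of information-gain statistics
#'
#' Calibrates observed statistics against a sample of null statistics (here:
#' per-variable `IG_max` values recomputed under label permutation). Within
#' the range of the null sample the p-value is the empirical permutation
#' upper-tail probability `(1 + #{null >= stat}) / (N + 1)`, which is valid
#' by exchangeability. Beyond the largest null value, where the empirical
#' tail has no resolution, the upper tail of a Gumbel (type-I extreme value)
#' distribution fitted to the null sample by maximum likelihood takes over
#' (capped at `1 / (N + 1)` so the two regimes join monotonically).
#'
#' @param statistics Observed statistics.
#' @param null_statistics At least 30 null statistics with positive variance.
#' @return p-values in `[0, 1]`, one per observed statistic; monotone
#'   non-increasing in the statistic.
#' @export
evd_significance <- function(statistics, null_statistics) {
  null <- as.numeric(null_statistics)
  if (length(null) < 30L) {
    stop("need at least 30 null statistics for the extreme-value fit", call. = FALSE)
  }
  if (stats::sd(null) == 0) {
    stop("degenerate null: zero variance", call. = FALSE)
  }
  stat <- as.numeric(statistics)
  N <- length(null)
  sorted <- sort(null)
  # #{null >= stat} via the number of null values strictly below each stat
  below <- findInterval(stat, sorted, left.open = TRUE)
  p_emp <- (1 + (N - below)) / (N + 1)
  fit <- fit_gumbel(null)
  z <- (stat - fit$loc) / fit$scale
  p_tail <- pmin(-expm1(-exp(-z)), 1 / (N + 1))
  p <- ifelse(stat > sorted[N], p_tail, p_emp)
  pmin(pmax(p, 0), 1)
}

#' Maximum-likelihood Gumbel fit
#'
#' @param x Numeric sample.
#' @return A list with `loc` and `scale` of the fitted Gumbel distribution.
#' @export
fit_gumbel <- function(x) {
  s0 <- sqrt(6) * stats::sd(x) / pi
  m0 <- mean(x) - 0.5772156649015329 * s0
  nll <- function(par) {
    b <- exp(par[2])
    z <- (x - par[1]) / b
    v <- length(x) * par[2] + sum(z) + sum(exp(-z))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(c(m0, log(s0)), nll, method = "BFGS")
  list(loc = opt$par[1], scale = exp(opt$par[2]))
}

# shared driver for the IG filters: permutation null + repeated
# discretizations, EVD calibration, Hochberg correction
.ig_filter <- function(dataset, disc, alpha, n_permutations, pairwise, method) {
  .check_complete(dataset)
  m <- ncol(dataset$x)
  if (m < 2L) {
    stop("information-gain filters need at least 2 variables", call. = FALSE)
  }
  y <- dataset$labels
  n <- length(y)
  seeds <- spawn_seeds(disc$seed, 2L)
  Ymat <- with_seed(seeds[1], {
    cbind(y, vapply(seq_len(n_permutations), function(i) sample(y),
                    integer(n)))
  })
  V <- ncol(Ymat)
  acc <- if (pairwise) lapply(seq_len(V), function(v) matrix(0, m, m))
         else matrix(0, m, V)
  with_seed(seeds[2], {
    for (s in seq_len(disc$n_random_splits)) {
      bins <- .disc_split(dataset$x, disc$n_bins)
      if (pairwise) {
        Mv <- .ig2d_split(bins, Ymat, disc$n_bins)
        for (v in seq_len(V)) acc[[v]] <- acc[[v]] + Mv[[v]]
      } else {
        acc <- acc + .ig1d_split(bins, Ymat, disc$n_bins)
      }
    }
  })
  if (pairwise) {
    stats_all <- vapply(acc, function(M) {
      apply(M / disc$n_random_splits, 1, max, na.rm = TRUE)
    }, numeric(m))
  } else {
    stats_all <- acc / disc$n_random_splits
  }
  stat <- stats_all[, 1]
  null <- as.vector(stats_all[, -1, drop = FALSE])
  p_raw <- evd_significance(stat, null)
  .filter_result(method, variable_ids(dataset), unname(stat), p_raw, alpha,
                 binning = disc)
}

#' Univariate information-gain filter (IG-1D)
#'
#' Scores each variable by its mutual information with the class label,
#' `IG(Y; x)`, averaged over repeated randomized equal-frequency
#' discretizations. Significance is calibrated against the statistic's
#' distribution under label permutation via [evd_significance()], followed by
#' the Hochberg correction.
#'
#' @param dataset A complete [cohort_dataset()].
#' @param disc A [discretization()].
#' @param alpha Significance level after correction.
#' @param n_permutations Label permutations pooled into the null sample.
#' @return A `filter_result` with method `"ig_1d"`.
#' @export
ig1d_filter <- function(dataset, disc = discretization(), alpha = 0.05,
                        n_permutations = 20L) {
  .ig_filter(dataset, disc, alpha, n_permutations, pairwise = FALSE,
             method = "ig_1d")
}

#' Pairwise conditional information-gain filter (IG-2D)
#'
#' Scores each variable `x_i` by `IG_max(x_i) = max_j IG(Y; x_i | x_j)` over
#' all other variables `x_j` (exhaustive pair scan), detecting variables
#' whose information about the label only appears jointly with a partner
#' (statistical synergy, e.g. XOR structure). The per-pair conditional
#' information gain is averaged over repeated randomized discretizations
#' before the maximum is taken. Significance via [evd_significance()] on the
#' permutation null of `IG_max`, then Hochberg correction.
#'
#' @inheritParams ig1d_filter
#' @return A `filter_result` with method `"ig_2d"`.
#' @export
ig2d_filter <- function(dataset, disc = discretization(), alpha = 0.05,
                        n_permutations = 20L) {
  .ig_filter(dataset, disc, alpha, n_permutations, pairwise = TRUE,
             method = "ig_2d")
}

#' Select variables along a lasso regularization path
#'
#' Fits an L1-regularized logistic model of the class label on the t-test
#' relevant set and walks the decreasing regularization path to the first
#' point where at least `n_target` coefficients are non-zero; overshoot is
#' truncated to the `n_target` coefficients of largest magnitude. If the path
#' never reaches `n_target` active variables the largest active set attained
#' is returned.
#'
#' @param dataset A complete [cohort_dataset()].
#' @param prefilter A `filter_result` with method `"t_test"` and a non-empty
#'   relevant set.
#' @param n_target Requested model dimension.
#' @return Character vector of selected variable ids.
#' @export
lasso_select <- function(dataset, prefilter, n_target) {
  if (!inherits(prefilter, "filter_result") || prefilter$method != "t_test") {
    stop("`prefilter` must be a t_test filter_result", call. = FALSE)
  }
  rel <- prefilter$relevant_ids
  if (!length(rel)) {
    stop("prefilter has an empty relevant set; nothing to select from",
         call. = FALSE)
  }
  n_target <- check_count(n_target, "n_target", min = 1)
  if (n_target >= length(rel) || length(rel) < 2L) {
    return(rel)
  }
  x <- dataset$x[, rel, drop = FALSE]
  fit <- glmnet::glmnet(x, factor(dataset$labels), family = "binomial",
                        nlambda = 100)
  k <- which(fit$df >= n_target)[1]
  if (is.na(k)) k <- which.max(fit$df)
  beta <- fit$beta[, k]
  active <- beta[beta != 0]
  ids <- names(active)[order(-abs(active), names(active))]
  utils::head(ids, n_target)
}

#' Top-N variables of a filter result
#'
#' Returns the `n` variable ids with smallest adjusted p-value; ties are
#' broken by larger absolute statistic, then lexicographic id. If fewer than
#' `n` variables are scored, all are returned.
#'
#' @param result A `filter_result`.
#' @param n Number of variables requested, at least 1.
#' @return Character vector of at most `n` variable ids.
#' @export
top_n <- function(result, n) {
  n <- check_count(n, "n", min = 1)
  sc <- result$scores
  o <- order(sc$p_adjusted, -abs(sc$statistic), sc$variable_id)
  utils::head(sc$variable_id[o], n)
}

#' Run a filter and select a feature subset
#'
#' Dispatcher used by the evaluation protocol. Runs the requested filter and
#' returns the selected ids: the top `n_features` by adjusted p-value when at
#' least `n_features` variables are relevant; the whole relevant set when it
#' is smaller but non-empty (as with copy-number data, where only a handful
#' of variables pass the filter); and, when no variable is relevant, the
#' best-ranked `n_features` regardless of significance, with a warning. For
#' `"t_test_lasso"` the t-test relevant set is refined by [lasso_select()].
#'
#' @param dataset A complete [cohort_dataset()].
#' @param method One of `"t_test"`, `"ig_1d"`, `"ig_2d"`, `"t_test_lasso"`.
#' @param n_features Requested subset size.
#' @param alpha Significance level after correction.
#' @param disc A [discretization()] template for the IG methods.
#' @param seed Seed overriding `disc$seed` (so cross-validation folds get
#'   independent discretization/permutation streams).
#' @param n_permutations Permutations for the IG null.
#' @return A list with `feature_ids`, `filter` (the `filter_result`), and
#'   `fallback` (logical: the zero-relevant fallback was taken).
#' @export
select_features <- function(dataset,
                            method = c("t_test", "ig_1d", "ig_2d", "t_test_lasso"),
                            n_features, alpha = 0.05, disc = discretization(),
                            seed = NULL, n_permutations = 20L) {
  method <- match.arg(method)
  n_features <- check_count(n_features, "n_features", min = 1)
  if (!is.null(seed)) disc$seed <- check_count(seed, "seed", min = 0)
  res <- switch(method,
    t_test = ,
    t_test_lasso = t_test_filter(dataset, alpha),
    ig_1d = ig1d_filter(dataset, disc, alpha, n_permutations),
    ig_2d = ig2d_filter(dataset, disc, alpha, n_permutations))
  rel <- res$relevant_ids
  fallback <- FALSE
  if (!length(rel)) {
    ids <- top_n(res, n_features)
    fallback <- TRUE
    warning(sprintf("%s found no relevant variables; using ranked top-%d",
                    method, n_features), call. = FALSE)
  } else if (method == "t_test_lasso") {
    ids <- lasso_select(dataset, res, n_features)
  } else if (length(rel) >= n_features) {
    ids <- top_n(res, n_features)
  } else {
    ids <- rel
  }
  list(feature_ids = ids, filter = res, fallback = fallback)
}

#' Write per-variable filter scores as CSV
#' @param result A `filter_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_scores <- function(result, path) {
  utils::write.csv(result$scores, path, row.names = FALSE)
  invisible(path)
}

#' Summarize relevant-set sizes across filter results
#'
#' @param results A list of `filter_result` objects.
#' @return A data frame with one row per result: method, alpha, number of
#'   variables scored and number relevant.
#' @export
relevant_set_summary <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, alpha = r$alpha,
               n_scored = nrow(r$scores),
               n_relevant = length(r$relevant_ids),
               stringsAsFactors = FALSE)
  }))
}
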