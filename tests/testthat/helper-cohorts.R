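# Fixture builders shared across tests. Everything is generated in code so
# the suite needs no stored data.

# small all-null gaussian cohort
null_cohort <- function(n1 = 15, n0 = 45, m = 20, seed = 1) {
  synforest:::with_seed(seed, {
    x <- matrix(rnorm((n1 + n0) * m), n1 + n0, m)
    cohort_dataset(x, c(rep(1L, n1), rep(0L, n0)))
  })
}

# build a variable block against a *given* label vector, so two blocks with
# independent signal on the same cohort can be constructed
signal_block <- function(labels, n_marginal = 3, effect = 1, n_null = 20,
                         seed = 1, tag = "MA", prefix = "B") {
  synforest:::with_seed(seed, {
    n <- length(labels)
    m <- n_marginal + n_null
    x <- matrix(rnorm(n * m), n, m)
    if (n_marginal > 0) {
      x[labels == 1L, seq_len(n_marginal)] <-
        x[labels == 1L, seq_len(n_marginal)] + effect
    }
    colnames(x) <- paste0(prefix, seq_len(m))
    cohort_dataset(x, labels, source_tags = rep(tag, m))
  })
}

# filter_result stub for functions that only consume $scores / $relevant_ids
fake_filter_result <- function(ids, statistic, p_adjusted,
                               method = "t_test", alpha = 0.05,
                               p_raw = p_adjusted) {
  o <- order(p_adjusted, -abs(statistic), ids)
  rk <- integer(length(ids)); rk[o] <- seq_along(ids)
  structure(list(method = method,
                 scores = data.frame(variable_id = ids, statistic = statistic,
                                     p_raw = p_raw, p_adjusted = p_adjusted,
                                     rank = rk, stringsAsFactors = FALSE),
                 relevant_ids = ids[o][p_adjusted[o] <= alpha],
                 alpha = alpha, binning = NULL),
            class = "filter_result")
}

# stage_result stub for bookkeeping-level functions
fake_stage_result <- function(stage, oob, cv = NA_real_, method = "t_test",
                              n_features = 10, predictions = NULL,
                              labels = NULL) {
  models <- data.frame(repeat_ = seq_along(oob), fold = 1L, mcc_oob = oob,
                       mcc_train = 1, mcc_validation = cv, seed = 1L)
  synforest:::.stage_result(stage, method, n_features, models,
                            feature_lists = list(), predictions = predictions,
                            labels = labels)
}

# direct stratified mutual-information oracle, independent of the
# four-entropy identity used by the implementation
oracle_cmi <- function(y, x, s = NULL) {
  strata <- if (is.null(s)) factor(rep(1, length(y)))
            else interaction(as.data.frame(s), drop = TRUE)
  tot <- 0
  for (sv in levels(strata)) {
    sel <- strata == sv
    if (!any(sel)) next
    ps <- mean(sel)
    tab <- table(x[sel], y[sel])
    pxy <- tab / sum(tab)
    px <- rowSums(pxy); py <- colSums(pxy)
    for (i in seq_along(px)) for (j in seq_along(py)) {
      if (pxy[i, j] > 0) {
        tot <- tot + ps * pxy[i, j] * log2(pxy[i, j] / (px[i] * py[j]))
      }
    }
  }
  unname(tot)
}

# light discretization profile used throughout the tests
quick_disc <- function(seed = 1, splits = 5, bins = 2) {
  discretization(n_bins = bins, n_random_splits = splits, seed = seed)
}
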