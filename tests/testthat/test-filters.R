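# --- Welch t ---------------------------------------------------------------

test_that("welch_t matches the closed form and the stats::t.test oracle", {
  r <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$t, -1.2247, tolerance = 1e-4)

  synforest:::with_seed(8, {
    for (i in 1:20) {
      a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
      b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
      got <- welch_t(a, b)
      ref <- t.test(a, b)   # Welch by default
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("welch_t symmetry, antisymmetry and degenerate cases", {
  expect_equal(welch_t(c(1, 2), c(1, 2)), list(t = 0, p_raw = 1))
  a <- c(0.3, 1.2, -0.5); b <- c(1.1, 0.2, 0.9, 1.4)
  expect_equal(welch_t(a, b)$t, -welch_t(b, a)$t)
  expect_equal(welch_t(c(2, 2), c(2, 2)), list(t = 0, p_raw = 1))
  expect_error(welch_t(c(2, 2), c(3, 3)), "degenerate")
  expect_error(welch_t(1, c(1, 2)), "2 observations")
})

test_that("the vectorized t-test filter agrees with the scalar operation", {
  d <- signal_block(rep(c(1L, 0L), c(12, 28)), n_marginal = 2, effect = 1.5,
                    n_null = 8, seed = 3)
  res <- t_test_filter(d)
  for (j in c(1, 5, 10)) {
    ref <- welch_t(d$x[d$labels == 1L, j], d$x[d$labels == 0L, j])
    expect_equal(res$scores$statistic[j], ref$t, tolerance = 1e-12)
    expect_equal(res$scores$p_raw[j], ref$p_raw, tolerance = 1e-12)
  }
  expect_equal(res$scores$p_adjusted, hochberg_adjust(res$scores$p_raw))
  expect_setequal(res$relevant_ids,
                  res$scores$variable_id[res$scores$p_adjusted <= 0.05])
})

# --- Hochberg --------------------------------------------------------------

test_that("hochberg_adjust reproduces the step-up recursion and p.adjust bounds", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p); ps <- p[o]
    adj <- numeric(m); adj[m] <- ps[m]
    if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i + 1], (m - i + 1) * ps[i])
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  expect_equal(hochberg_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.04, 0.5))
  expect_equal(hochberg_adjust(0.2), 0.2)
  expect_equal(hochberg_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(hochberg_adjust(numeric(0)), numeric(0))
  expect_error(hochberg_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  synforest:::with_seed(17, {
    for (i in 1:200) {
      p <- runif(sample(1:12, 1))^sample(1:3, 1)
      adj <- hochberg_adjust(p)
      expect_equal(adj, step_up(p), tolerance = 1e-12)
      # step-up dominance: Bonferroni set <= Hochberg set <= uncorrected set
      alpha <- 0.05
      expect_true(all(which(pmin(p * length(p), 1) <= alpha)
                      %in% which(adj <= alpha)))
      expect_true(all(which(adj <= alpha) %in% which(p <= alpha)))
    }
  })
})

# --- Entropy and conditional information gain ------------------------------

test_that("shannon_entropy handles the canonical contingencies", {
  expect_equal(shannon_entropy(c(5, 5)), 1.0)
  expect_equal(shannon_entropy(c(10, 0)), 0.0)
  expect_equal(shannon_entropy(c(3, 1)), 0.8113, tolerance = 1e-4)
  expect_error(shannon_entropy(c(0, 0)), "positive total")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("conditional_ig resolves the XOR triple exactly", {
  # all 4 balanced combinations of (x1, x2), y = xor
  x1 <- c(0, 0, 1, 1); x2 <- c(0, 1, 0, 1); y <- as.integer(xor(x1, x2))
  expect_equal(conditional_ig(y, x1), 0.0)
  expect_equal(conditional_ig(y, x2), 0.0)
  expect_equal(conditional_ig(y, x1, x2), 1.0)
  expect_equal(conditional_ig(y, x2, x1), 1.0)
  # self-information of a fair bit; independence gives zero
  yb <- rep(c(0, 1), 8)
  expect_equal(conditional_ig(yb, yb), 1.0)
  expect_equal(conditional_ig(yb, rep(3, 16)), 0.0)
  expect_equal(conditional_ig(yb, rep(3, 16), rep(c(1, 2), each = 8)), 0.0)
  expect_error(conditional_ig(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("conditional_ig equals the joint-count oracle on small discrete inputs", {
  synforest:::with_seed(23, {
    for (i in 1:150) {
      n <- sample(10:60, 1)
      ky <- sample(2:3, 1); kx <- sample(2:5, 1)
      y <- sample.int(ky, n, replace = TRUE)
      x <- sample.int(kx, n, replace = TRUE)
      ns <- sample(0:2, 1)
      s <- if (ns == 0) NULL
           else replicate(ns, sample.int(sample(2:5, 1), n, replace = TRUE),
                          simplify = FALSE)
      got <- conditional_ig(y, x, s)
      expect_equal(got, oracle_cmi(y, x, s), tolerance = 1e-12)
      expect_gte(got, 0)
    }
  })
})

# --- EVD significance ------------------------------------------------------

test_that("fit_gumbel recovers parameters of a Gumbel sample", {
  x <- synforest:::with_seed(5, 1.7 - 0.4 * log(-log(runif(5000))))
  fit <- fit_gumbel(x)
  expect_equal(fit$loc, 1.7, tolerance = 0.03)
  expect_equal(fit$scale, 0.4, tolerance = 0.05)
})

test_that("evd_significance is monotone and matches the empirical tail", {
  null <- synforest:::with_seed(6, -log(-log(runif(400))))
  p <- evd_significance(c(max(null), median(null), min(null)), null)
  expect_lte(p[1], 1 / length(null) + 0.01)
  expect_gt(p[2], 0.4)
  expect_true(all(diff(p) >= 0))   # larger statistic never has larger p
  q <- seq(min(null), max(null), length.out = 50)
  expect_true(all(diff(evd_significance(q, null)) <= 1e-12))
  expect_error(evd_significance(1, rep(2, 100)), "degenerate")
  expect_error(evd_significance(1, rnorm(10)), "at least 30")
})

# --- IG filters ------------------------------------------------------------

test_that("IG-2D statistic equals an independent double-loop reference", {
  labels <- rep(c(1L, 0L), c(10, 20))
  d <- signal_block(labels, n_marginal = 2, effect = 1.5, n_null = 4, seed = 12)
  disc <- quick_disc(seed = 31, splits = 3)
  n_perm <- 20L
  res <- ig2d_filter(d, disc, n_permutations = n_perm)

  m <- ncol(d$x); n <- nrow(d$x)
  seeds <- synforest:::spawn_seeds(disc$seed, 2L)
  synforest:::with_seed(seeds[1],
    replicate(n_perm, sample(labels)))  # consume the permutation stream
  acc <- matrix(0, m, m)
  synforest:::with_seed(seeds[2], {
    for (s in seq_len(disc$n_random_splits)) {
      bins <- synforest:::.disc_split(d$x, disc$n_bins)
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i != j) acc[i, j] <- acc[i, j] +
            conditional_ig(labels, bins[, i], bins[, j])
      }
    }
  })
  ref_stat <- apply(acc / disc$n_random_splits, 1, max)
  expect_equal(res$scores$statistic, ref_stat, tolerance = 1e-12)
})

test_that("IG-1D statistic equals the scalar mutual-information path", {
  labels <- rep(c(1L, 0L), c(12, 24))
  d <- signal_block(labels, n_marginal = 1, effect = 2, n_null = 5, seed = 14)
  disc <- quick_disc(seed = 7, splits = 4)
  res <- ig1d_filter(d, disc, n_permutations = 20)
  m <- ncol(d$x)
  seeds <- synforest:::spawn_seeds(disc$seed, 2L)
  synforest:::with_seed(seeds[1], replicate(20, sample(labels)))
  acc <- numeric(m)
  synforest:::with_seed(seeds[2], {
    for (s in seq_len(disc$n_random_splits)) {
      bins <- synforest:::.disc_split(d$x, disc$n_bins)
      acc <- acc + vapply(seq_len(m),
                          function(j) conditional_ig(labels, bins[, j]), 0)
    }
  })
  expect_equal(res$scores$statistic, acc / disc$n_random_splits,
               tolerance = 1e-12)
})

test_that("IG-1D ranks planted marginal variables above the null bulk", {
  hits <- 0L; total <- 0L
  for (i in seq_len(100)) {
    g <- generate_cohort(synthetic_spec(n_minority = 38, n_majority = 107,
                                        n_null = 50, n_marginal = 5,
                                        marginal_effect = 1.5,
                                        n_synergy_pairs = 0, seed = 500 + i))
    res <- ig1d_filter(g$dataset, quick_disc(seed = i, splits = 5))
    sc <- res$scores
    null_stats <- sc$statistic[sc$variable_id %in% g$ground_truth$null_ids]
    thr <- quantile(null_stats, 0.95)
    for (id in g$ground_truth$marginal_ids) {
      total <- total + 1L
      if (sc$statistic[sc$variable_id == id] > thr) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("IG-2D keeps the false-positive rate down at m = 2", {
  clean <- 0L
  for (i in seq_len(100)) {
    d <- null_cohort(12, 28, m = 2, seed = 900 + i)
    res <- ig2d_filter(d, quick_disc(seed = i, splits = 5))
    expect_true(all(is.finite(res$scores$statistic)))
    if (length(res$relevant_ids) == 0) clean <- clean + 1L
  }
  expect_gte(clean / 100, 0.94)
})

test_that("duplicated variables receive identical IG statistics", {
  labels <- rep(c(1L, 0L), c(10, 20))
  b <- signal_block(labels, n_marginal = 1, effect = 1, n_null = 2, seed = 3)
  x <- cbind(b$x, dup = b$x[, 1])
  d <- cohort_dataset(x, labels)
  res <- ig1d_filter(d, quick_disc(seed = 2, splits = 10))
  sc <- res$scores
  expect_equal(sc$statistic[sc$variable_id == "B1"],
               sc$statistic[sc$variable_id == "dup"], tolerance = 0.02)
})

# --- lasso and top-N -------------------------------------------------------

test_that("lasso_select saturates, validates, and recovers planted variables", {
  labels <- rep(c(1L, 0L), c(15, 35))
  d <- signal_block(labels, n_marginal = 3, effect = 2, n_null = 10, seed = 21)
  pre <- t_test_filter(d)
  expect_gt(length(pre$relevant_ids), 0)
  expect_setequal(lasso_select(d, pre, 50), pre$relevant_ids)
  expect_error(lasso_select(d, ig1d_filter(d, quick_disc()), 5), "t_test")
  empty <- fake_filter_result("a", 1, 0.9)
  expect_error(lasso_select(d, empty, 2), "empty relevant set")
  # deterministic given fixed data and path grid
  d2 <- signal_block(labels, n_marginal = 5, effect = 2, n_null = 30, seed = 4)
  pre2 <- t_test_filter(d2)
  expect_identical(lasso_select(d2, pre2, 3), lasso_select(d2, pre2, 3))

  # Monte-Carlo recovery of 5 strong marginals among 50 nulls
  hits <- 0L
  for (i in seq_len(100)) {
    g <- generate_cohort(synthetic_spec(n_minority = 38, n_majority = 107,
                                        n_null = 50, n_marginal = 5,
                                        marginal_effect = 2,
                                        n_synergy_pairs = 0, seed = 3000 + i))
    pre <- t_test_filter(g$dataset)
    if (!length(pre$relevant_ids)) next
    sel <- lasso_select(g$dataset, pre, 5)
    if (setequal(sel, g$ground_truth$marginal_ids)) hits <- hits + 1L
  }
  expect_gte(hits / 100, 0.90)
})

test_that("top_n honours p-value order and the stated tie rules", {
  res <- fake_filter_result(
    ids = c("a", "b", "c", "d"),
    statistic = c(1.0, 2.0, 3.0, 0.5),
    p_adjusted = c(0.02, 0.02, 0.001, 0.8))
  expect_identical(top_n(res, 10), c("c", "b", "a", "d"))  # n > m -> all
  expect_identical(top_n(res, 1), "c")
  expect_identical(top_n(res, 2), c("c", "b"))  # tie at p = .02: |stat| 2 > 1
  expect_error(top_n(res, 0), "n")
})

test_that("select_features falls back to ranked top-N only when nothing is relevant", {
  d <- null_cohort(12, 28, 15, seed = 77)
  expect_warning(sel <- select_features(d, "t_test", 5), "no relevant")
  expect_length(sel$feature_ids, 5)
  expect_true(sel$fallback)

  labels <- rep(c(1L, 0L), c(15, 35))
  ds <- signal_block(labels, n_marginal = 3, effect = 2, n_null = 10, seed = 8)
  sel2 <- select_features(ds, "t_test", 10)
  expect_false(sel2$fallback)
  # fewer relevant than requested -> the whole relevant set, no padding
  expect_setequal(sel2$feature_ids, t_test_filter(ds)$relevant_ids)
})
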