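#' Specification of a synthetic cohort
#'
#' Describes a cohort with the statistical structure the downstream analysis
#' assumes: a strongly unbalanced binary outcome, marginally informative
#' variables with a chosen standardized effect size, purely synergistic
#' variable pairs that are jointly but not marginally informative, and null
#' variables. Defaults emulate a 145-patient cohort with 38 non-survivors
#' (about 26% minority class).
#'
#' @param n_minority,n_majority Class sizes; `n_minority` is the positive
#'   (non-survivor) class and may not exceed `n_majority`.
#' @param n_null Number of label-independent variables.
#' @param n_marginal Number of marginally informative variables.
#' @param marginal_effect Standardized difference of class means (Cohen's d
#'   units; per-class SD is 1) for each marginal variable.
#' @param n_synergy_pairs Number of planted XOR-style pairs. Each member is
#'   marginally independent of the label but the sign product of the pair
#'   shifts the class-conditional probability.
#' @param synergy_strength Class-probability shift per pair, in `[0, 0.5]`.
#'   At 0.5 the sign product determines the class deterministically.
#' @param noise_model One of `"gaussian"` (microarray-like, normal per class
#'   on log scale), `"lognormal_count"` (RNA-seq-like: skewed, non-negative,
#'   with excess zeros), `"cnv_gaussian"` (copy-number-like: approximately
#'   normal, roughly in \[-3, 3\], with missing entries).
#' @param missing_rate Fraction of entries set missing for `cnv_gaussian`
#'   variables, in `[0, 1)`.
#' @param zero_fraction Fraction of entries floored to zero for
#'   `lognormal_count` variables.
#' @param seed Integer seed; a fixed seed yields a bit-identical dataset.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_minority = 38, n_majority = 107,
                           n_null = 400, n_marginal = 20, marginal_effect = 1.0,
                           n_synergy_pairs = 5, synergy_strength = 0.2,
                           noise_model = c("gaussian", "lognormal_count", "cnv_gaussian"),
                           missing_rate = 0.1, zero_fraction = 0.2, seed = 1) {
  spec <- list(
    n_minority = check_count(n_minority, "n_minority", min = 1),
    n_majority = check_count(n_majority, "n_majority", min = 1),
    n_null = check_count(n_null, "n_null"),
    n_marginal = check_count(n_marginal, "n_marginal"),
    marginal_effect = check_fraction(marginal_effect, "marginal_effect", 0, Inf),
    n_synergy_pairs = check_count(n_synergy_pairs, "n_synergy_pairs"),
    synergy_strength = check_fraction(synergy_strength, "synergy_strength", 0, 0.5),
    noise_model = match.arg(noise_model),
    missing_rate = check_fraction(missing_rate, "missing_rate", 0, 1, hi_open = TRUE),
    zero_fraction = check_fraction(zero_fraction, "zero_fraction", 0, 1, hi_open = TRUE),
    seed = check_count(seed, "seed", min = 0)
  )
  if (spec$n_minority > spec$n_majority) {
    stop_field("n_minority", "may not exceed n_majority")
  }
  if (spec$n_null + spec$n_marginal + 2L * spec$n_synergy_pairs < 1L) {
    stop_field("n_null", "the cohort must contain at least one variable")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Draws a cohort per a [synthetic_spec()]. Marginal variables differ in class
#' means by `marginal_effect` per-class standard deviations. Each synergy pair
#' `(z1, z2)` is built from standard normal draws whose sign product
#' `sign(z1 * z2)` carries the class information: the probability of a
#' positive sign product is `0.5 + synergy_strength` in the minority class and
#' `0.5 - synergy_strength` in the majority class, while each member remains
#' marginally standard normal within both classes (expected marginal effect
#' zero). Null variables are label-independent. The noise model is then
#' applied: `lognormal_count` exponentiates the latent values and floors a
#' random `zero_fraction` of entries to zero; `cnv_gaussian` keeps the latent
#' scale and sets entries missing at `missing_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `dataset` (a [cohort_dataset()]) and
#'   `ground_truth` (list of `marginal_ids`, `synergy_pair_ids`, `null_ids`,
#'   which partition the variables).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  with_seed(spec$seed, {
    n <- spec$n_minority + spec$n_majority
    labels <- sample(c(rep(1L, spec$n_minority), rep(0L, spec$n_majority)))

    marginal_ids <- if (spec$n_marginal > 0)
      sprintf("M%03d", seq_len(spec$n_marginal)) else character(0)
    pair_ids <- if (spec$n_synergy_pairs > 0)
      lapply(seq_len(spec$n_synergy_pairs),
             function(i) c(sprintf("S%03da", i), sprintf("S%03db", i)))
      else list()
    null_ids <- if (spec$n_null > 0)
      sprintf("N%04d", seq_len(spec$n_null)) else character(0)

    blocks <- list()
    if (spec$n_marginal > 0) {
      z <- matrix(stats::rnorm(n * spec$n_marginal), n, spec$n_marginal)
      z[labels == 1L, ] <- z[labels == 1L, ] + spec$marginal_effect
      colnames(z) <- marginal_ids
      blocks <- c(blocks, list(z))
    }
    for (pr in pair_ids) {
      z1 <- stats::rnorm(n)
      z2 <- stats::rnorm(n)
      p_plus <- 0.5 + ifelse(labels == 1L, 1, -1) * spec$synergy_strength
      s <- ifelse(stats::runif(n) < p_plus, 1, -1)
      # force sign(z1 * z2) == s; |z2| is untouched, so z2 stays N(0,1)
      # marginally in each class (sign(z1) is symmetric and label-free)
      z2 <- s * sign(z1) * abs(z2)
      zz <- cbind(z1, z2)
      colnames(zz) <- pr
      blocks <- c(blocks, list(zz))
    }
    if (spec$n_null > 0) {
      z <- matrix(stats::rnorm(n * spec$n_null), n, spec$n_null)
      colnames(z) <- null_ids
      blocks <- c(blocks, list(z))
    }
    x <- do.call(cbind, blocks)

    tag <- switch(spec$noise_model,
                  gaussian = "MA", lognormal_count = "G", cnv_gaussian = "CNV")
    if (spec$noise_model == "lognormal_count") {
      x <- exp(x)
      if (spec$zero_fraction > 0) {
        zero <- matrix(stats::runif(length(x)) < spec$zero_fraction,
                       nrow(x), ncol(x))
        x[zero] <- 0
      }
    } else if (spec$noise_model == "cnv_gaussian" && spec$missing_rate > 0) {
      miss <- matrix(stats::runif(length(x)) < spec$missing_rate,
                     nrow(x), ncol(x))
      x[miss] <- NA_real_
    }

    dataset <- cohort_dataset(x, labels,
                              source_tags = rep(tag, ncol(x)))
    list(dataset = dataset,
         ground_truth = list(marginal_ids = marginal_ids,
                             synergy_pair_ids = pair_ids,
                             null_ids = null_ids))
  })
}

#' Inject missing values completely at random
#'
#' Sets each entry of the targeted variables missing independently with the
#' given probability (MCAR); labels are untouched.
#'
#' @param dataset A [cohort_dataset()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the same mask.
#' @param variables Variable ids to target (default: all).
#' @return The dataset with missing entries injected.
#' @export
inject_missingness <- function(dataset, rate, seed, variables = NULL) {
  rate <- check_fraction(rate, "rate", 0, 1, hi_open = TRUE)
  if (rate == 0) return(dataset)
  j <- if (is.null(variables)) seq_len(ncol(dataset$x))
       else match(variables, variable_ids(dataset))
  if (anyNA(j)) stop("unknown variable id(s) in `variables`", call. = FALSE)
  with_seed(seed, {
    block <- dataset$x[, j, drop = FALSE]
    mask <- matrix(stats::runif(length(block)) < rate, nrow(block), ncol(block))
    block[mask] <- NA_real_
    dataset$x[, j] <- block
  })
  dataset
}

#' Write the ground truth of a synthetic cohort as JSON
#' @param ground_truth The `ground_truth` element of [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path Input path.
#' @return A ground-truth list as produced by [generate_cohort()].
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$synergy_pair_ids <- lapply(seq_len(NROW(gt$synergy_pair_ids)), function(i) {
    if (is.matrix(gt$synergy_pair_ids)) gt$synergy_pair_ids[i, ]
    else unlist(gt$synergy_pair_ids[[i]])
  })
  gt
}
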