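# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All randomness in the package funnels
# through this so that a master seed yields bit-identical results.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically spawn `n` child seeds from one root seed; used to give
# every (repeat, fold, purpose) its own stream.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# -x * log2(x) summed over the cells of a count array, normalised by `total`.
# Zero cells contribute zero by the usual convention. Keeps dims.
plogp_bits <- function(counts, total) {
  out <- counts
  out[] <- 0
  nz <- counts > 0
  p <- counts[nz] / total
  out[nz] <- -p * log2(p)
  out
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_field(field, sprintf("must be a number in %s%g, %g%s",
                              if (lo_open) "(" else "[", lo, hi,
                              if (hi_open) ")" else "]"))
  }
  as.numeric(x)
}
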