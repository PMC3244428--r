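# Internal helpers shared across modules.

# Smallest allele frequency kept after Balding-Nichols sampling; avoids
# monomorphic columns that break the PCA normalization.
FREQ_EPS <- 1e-4

# Median of the chi-square(1 df) distribution, the denominator of the
# median-based Genomic Control estimator.
CHISQ1_MEDIAN <- 0.4549364

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  ok_low <- if (open_lower) x > lower else x >= lower
  ok_up <- if (open_upper) x < upper else x <= upper
  if (!ok_low || !ok_up) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

# Counter-based per-replicate seed derivation: deterministic in
# (master seed, counter), stays below 2^31, and lets any replicate be
# re-run in isolation. Arithmetic is exact in doubles (< 2^53).
derive_seed <- function(master, counter) {
  m <- as.double(master) %% 2147483647
  s <- (m + as.double(counter) * 48271 + 1) %% 2147483647
  as.integer(s + 1)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}

# Format a numeric vector at 6 significant digits for the fixed-dialect TSV
# output (LF endings are handled by writeLines).
fmt6 <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) "NA"
    else format(signif(xi, 6L), trim = TRUE, scientific = FALSE, digits = 15L)
  }, character(1))
}
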