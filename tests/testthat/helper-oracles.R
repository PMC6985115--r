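# Independent oracles, kept free of the implementation paths they check.

# Full hypergeometric enumeration of the two-sided Fisher p-value on a
# 2x2 table with fixed margins: sum the point probabilities of every
# table no more probable than the observed one (relative tie tolerance
# 1e-7).
fisher_enumeration_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Adaptive quadrature of the origin-model marginal likelihood
# integral(Binom(k; n, th) * (1 - th)^n_wbc * Beta(th; a, b) dth),
# in log space via peak-scaled integration.
quadrature_logml_oracle <- function(k, n, n_wbc, a = 2.4, b = 340) {
  f_log <- function(th) stats::dbinom(k, n, th, log = TRUE) +
    stats::dbeta(th, a, b, log = TRUE) + n_wbc * log1p(-th)
  opt <- stats::optimize(f_log, c(1e-12, 1 - 1e-12), maximum = TRUE)
  mode <- opt$maximum
  peak <- opt$objective
  # Laplace width from a finite-difference second derivative; integrate a
  # generous multiple of it so sharp integrands are resolved
  h <- max(mode, 1e-8) * 1e-3
  fpp <- (f_log(mode + h) - 2 * peak + f_log(mode - h)) / h^2
  width <- if (is.finite(fpp) && fpp < 0) 1 / sqrt(-fpp) else 0.1
  lo <- max(1e-14, mode - 80 * width)
  hi <- min(1 - 1e-14, mode + 80 * width)
  val <- stats::integrate(function(th) exp(f_log(th) - peak), lo, hi,
                          rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 2000L)$value
  log(val) + peak
}

# Brute-force KS D: sup |ECDF_a - ECDF_b| evaluated over the pooled
# support.
ks_d_bruteforce <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
  fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
  max(abs(fa - fb))
}

# Row builder for toy observation tables.
make_obs <- function(patient_id = "P1", timepoint = "baseline",
                     compartment = "cfDNA", gene = "TP53",
                     chrom = "chr17", pos = 7577100L, ref = "C", alt = "T",
                     consequence = "missense", aa_change = "p.R175H",
                     n_distinct = 30000L, k_alt = 30L,
                     sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- paste(patient_id, timepoint, compartment, sep = "_")
  data.frame(patient_id = patient_id, sample_id = sample_id,
             timepoint = timepoint, compartment = compartment, gene = gene,
             chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             consequence = consequence, aa_change = aa_change,
             n_distinct = as.integer(n_distinct), k_alt = as.integer(k_alt),
             stringsAsFactors = FALSE)
}
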