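# Independent oracles, kept separate from the package's code paths.

# Hypergeometric pmf over the whole support, computed from log-factorials
# (lgamma), independent of stats::dhyper. Margins: row totals m, n2; first
# column total k.
hyper_pmf_oracle <- function(m, n2, k) {
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  lf <- function(v) lgamma(v + 1)
  exp(lf(m) - lf(x) - lf(m - x) +
      lf(n2) - lf(k - x) - lf(n2 - k + x) -
      (lf(m + n2) - lf(k) - lf(m + n2 - k)))
}

# Exhaustive two-sided Fisher p for every observable first cell: total mass
# of tables whose probability is <= the observed one (same tie tolerance the
# probability-mass definition requires).
fisher_pvals_oracle <- function(m, n2, k, tol = 1e-7) {
  pmf <- hyper_pmf_oracle(m, n2, k)
  vapply(seq_along(pmf), function(i) {
    min(1, sum(pmf[pmf <= pmf[i] * (1 + tol)]))
  }, numeric(1))
}

fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  fisher_pvals_oracle(m, n2, k)[a - max(0, k - n2) + 1]
}

# Closed-form 1-df chi-squared upper tail, p = erfc(sqrt(chi2 / 2)).
chisq_tail_oracle <- function(chi2) {
  pracma::erfc(sqrt(chi2 / 2))
}
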