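# Independent oracles used across test files.

# Sorting-based type-7 quantile: q at probability p is the linear
# interpolation between order statistics at index 1 + p*(n-1).
sort_quantile <- function(v, p) {
  s <- sort(v)
  h <- 1 + p * (length(s) - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Tukey fences computed entirely from the sorting-based quantile oracle.
oracle_tukey <- function(v) {
  ok <- !is.na(v)
  flags <- rep(FALSE, length(v))
  if (sum(ok) < 4L) return(flags)
  q1 <- sort_quantile(v[ok], 0.25)
  q3 <- sort_quantile(v[ok], 0.75)
  iqr <- q3 - q1
  flags[ok] <- v[ok] < q1 - 1.5 * iqr | v[ok] > q3 + 1.5 * iqr
  flags
}

# Standard-normal quantile via root finding on pnorm: an implementation of
# the inverse CDF independent of qnorm's algorithm.
oracle_qnorm <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(z) stats::pnorm(z) - pp, c(-40, 40),
                   tol = 1e-12)$root
  }, 0)
}

# correlated bivariate normal sampler used by several fixtures
rbvn <- function(n, rho, sd = 1, mean = 0) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(mean + sd * z1, mean + sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}
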