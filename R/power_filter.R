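#' Minimum sample size to support a correlation
#'
#' Fisher-z power analysis for the two-sided test of rho = 0: the smallest n
#' for which a true correlation of magnitude `r` is detected with the stated
#' power at significance level `alpha`,
#' \deqn{n = \lceil ((z_{1-\alpha/2} + z_{power}) / \mathrm{atanh}(r))^2 + 3 \rceil}
#' using the +3 small-sample correction of the Fisher transformation. At the
#' defaults (alpha 0.001, power 0.8) a correlation of 0.85 requires 14
#' samples.
#'
#' @param r Correlation magnitude, strictly between 0 and 1.
#' @param alpha Type I error rate (default 0.001).
#' @param power 1 minus the Type II error rate (default 0.8).
#' @return Integer minimum sample size (always >= 4).
#' @examples
#' min_samples_for_correlation(0.85)  # 14
#' @export
min_samples_for_correlation <- function(r, alpha = 0.001, power = 0.8) {
  if (!is.finite(r) || r <= 0 || r >= 1) {
    stop("correlation magnitude must lie strictly between 0 and 1")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie strictly in (0, 1)")
  }
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(r)
  n <- as.integer(ceiling(z^2 + 3))
  max(n, 4L)
}

#' Filter clusters by correlation power
#'
#' A cluster survives iff its sample count is at least
#' [min_samples_for_correlation()] of its correlation magnitude.
#'
#' @param clusters Cluster data frame from [similarity_pass()].
#' @param alpha,power Power-analysis parameters.
#' @return The surviving rows, with the `run_log` attribute extended by the
#'   cluster counts entering and leaving this stage.
#' @export
apply_power_filter <- function(clusters, alpha = 0.001, power = 0.8) {
  if (nrow(clusters) == 0L) {
    keep <- logical(0)
  } else {
    need <- vapply(abs(clusters$r), function(a) {
      if (a >= 1) 4L else min_samples_for_correlation(a, alpha, power)
    }, 0L)
    keep <- clusters$cluster_size >= need
  }
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "run_log") <- c(attr(clusters, "run_log"),
                            power_in = nrow(clusters), power_out = nrow(out))
  out
}
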