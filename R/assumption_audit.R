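#' Royston test of bivariate normality
#'
#' Royston's multivariate extension of the Shapiro-Wilk test: each margin's
#' W statistic is transformed to an approximately standard-normal z (via the
#' Shapiro-Wilk normalization used by [stats::shapiro.test()]), the z's are
#' converted to chi-square-like contributions, and their sum is referred to
#' a chi-square distribution with equivalent degrees of freedom adjusted for
#' the correlation between the margins.
#'
#' @param x,y Paired observations, no missing values, 4 <= n <= 2000.
#' @return Upper-tail p-value; small values indicate departure from
#'   bivariate normality.
#' @export
royston_normality <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L || n > 2000L) {
    stop("Royston test requires 4 <= n <= 2000 (got ", n, ")")
  }
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant margin; returning p = 0 (degenerate)")
    return(0)
  }
  # margin z-scores from the Shapiro-Wilk normal approximation
  z <- vapply(list(x, y), function(m) {
    stats::qnorm(stats::shapiro.test(m)$p.value, lower.tail = FALSE)
  }, 0)
  psi <- stats::qnorm(pmin(stats::pnorm(-z) / 2, 0.5))^2
  psi[is.infinite(z) & z > 0] <- Inf
  u <- log(n)
  v <- 0.21364 + 0.015124 * u^2 - 0.0018034 * u^3
  r <- abs(stats::cor(x, y))
  cg <- r^5 * (1 - (0.715 / v) * (1 - r)^0.715)
  e <- 2 / (1 + cg)  # equivalent degrees of freedom, bivariate case
  h <- e * sum(psi) / 2
  if (!is.finite(h)) return(0)
  stats::pchisq(h, df = e, lower.tail = FALSE)
}

#' Breusch-Pagan test for heteroscedasticity of a gene pair
#'
#' OLS of y on x, then the Lagrange-multiplier form of the Breusch-Pagan
#' test: the squared residuals are regressed on x and `n * R^2` of that
#' auxiliary regression is referred to chi-square with 1 degree of freedom.
#'
#' @param x,y Paired observations; `x` must be non-constant, n >= 5.
#' @return Upper-tail p-value; small values indicate that the residual
#'   variance depends on `x`. A perfect fit (zero residuals) gives p = 1.
#' @export
breusch_pagan <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5L) stop("Breusch-Pagan test requires n >= 5")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0) stop("x is constant; regression design is degenerate")
  fit <- stats::lm.fit(cbind(1, x), y)
  # a (numerically) perfect fit carries no variance information: LM = 0
  if (max(abs(fit$residuals)) <= 1e-10 * (stats::sd(y) + 1e-300)) return(1)
  e2 <- fit$residuals^2
  if (stats::sd(e2) == 0) return(1)
  lm_stat <- n * stats::cor(e2, x)^2
  stats::pchisq(lm_stat, df = 1, lower.tail = FALSE)
}

#' Audit network edges for correlation-test assumptions
#'
#' For each edge, on the pairwise-complete (optionally Tukey-cleaned)
#' samples, tests bivariate normality (Royston), heteroscedasticity
#' (Breusch-Pagan) and multimodality (a bivariate Gaussian mixture fit
#' selecting K >= 2 components), then aggregates the failure fractions.
#'
#' @param gem GEM matrix.
#' @param edges Data frame with `gene_i` and `gene_j` columns (a ranked
#'   network table works directly). Duplicate pairs are audited once.
#' @param alpha Significance level for both assumption tests (default 0.01).
#' @param outlier_removal Apply the Tukey pre-clean before testing
#'   (default `TRUE`).
#' @param max_k,min_cluster_size,seed Mixture controls for the
#'   multimodality check; the audit's size floor defaults to 10 so that
#'   smaller secondary modes still count as multimodal.
#' @return List of class `csgcn_audit` with `n_edges_tested`,
#'   `n_edges_skipped`, `fraction_failing_normality`,
#'   `fraction_failing_equal_variance`, `fraction_failing_either`,
#'   `fraction_multimodal_among_nonnormal`, and `per_edge` (one row per
#'   audited pair with p-values and the selected K).
#' @export
audit_edges <- function(gem, edges, alpha = 0.01, outlier_removal = TRUE,
                        max_k = 5L, min_cluster_size = 10L, seed = 1L) {
  pairs <- unique(edges[, c("gene_i", "gene_j")])
  missing_genes <- setdiff(unique(c(pairs$gene_i, pairs$gene_j)),
                           rownames(gem))
  if (length(missing_genes) > 0L) {
    stop("edge gene(s) absent from GEM: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  rows <- vector("list", nrow(pairs))
  n_skipped <- 0L
  for (k in seq_len(nrow(pairs))) {
    x <- gem[pairs$gene_i[[k]], ]
    y <- gem[pairs$gene_j[[k]], ]
    ok <- !is.na(x) & !is.na(y)
    xs <- x[ok]; ys <- y[ok]
    if (outlier_removal && length(xs) >= 4L) {
      keep <- !(tukey_mask(xs) | tukey_mask(ys))
      xs <- xs[keep]; ys <- ys[keep]
    }
    if (length(xs) < 5L || length(xs) > 2000L ||
        stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    fit <- fit_pair_clusters(xs, ys, max_k = max_k,
                             min_cluster_size = min_cluster_size,
                             seed = .pair_seed(seed, k, k, nrow(pairs)))
    rows[[k]] <- data.frame(
      gene_i = pairs$gene_i[[k]], gene_j = pairs$gene_j[[k]],
      n_used = length(xs),
      royston_p = royston_normality(xs, ys),
      bp_p = breusch_pagan(xs, ys),
      K = fit$K, stringsAsFactors = FALSE)
  }
  per_edge <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per_edge)) {
    per_edge <- data.frame(gene_i = character(), gene_j = character(),
                           n_used = integer(), royston_p = numeric(),
                           bp_p = numeric(), K = integer(),
                           stringsAsFactors = FALSE)
  }
  per_edge$fails_normality <- per_edge$royston_p < alpha
  per_edge$fails_variance <- per_edge$bp_p < alpha
  per_edge$multimodal <- per_edge$K >= 2L
  nt <- nrow(per_edge)
  nonnormal <- per_edge[per_edge$fails_normality, , drop = FALSE]
  report <- list(
    n_edges_tested = nt,
    n_edges_skipped = n_skipped,
    fraction_failing_normality = if (nt) mean(per_edge$fails_normality) else NA_real_,
    fraction_failing_equal_variance = if (nt) mean(per_edge$fails_variance) else NA_real_,
    fraction_failing_either =
      if (nt) mean(per_edge$fails_normality | per_edge$fails_variance) else NA_real_,
    fraction_multimodal_among_nonnormal =
      if (nrow(nonnormal)) mean(nonnormal$multimodal) else NA_real_,
    alpha = alpha,
    per_edge = per_edge)
  class(report) <- "csgcn_audit"
  report
}

#' @export
print.csgcn_audit <- function(x, ...) {
  cat("Edge assumption audit (alpha =", x$alpha, ")\n")
  cat("  edges tested:          ", x$n_edges_tested,
      " (skipped ", x$n_edges_skipped, ")\n", sep = "")
  cat(sprintf("  failing normality:      %.3f\n", x$fraction_failing_normality))
  cat(sprintf("  failing equal variance: %.3f\n",
              x$fraction_failing_equal_variance))
  cat(sprintf("  failing either:         %.3f\n", x$fraction_failing_either))
  cat(sprintf("  multimodal | non-normal:%.3f\n",
              x$fraction_multimodal_among_nonnormal))
  invisible(x)
}
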