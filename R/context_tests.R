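#' Categorical context association for one cluster
#'
#' Two one-proportion z-tests (normal approximation, no continuity
#' correction) against the label's prevalence in the comparison set: the
#' first tests enrichment of the category inside the cluster (one-sided
#' greater), the second tests depletion of the category outside the cluster
#' (one-sided less). The association is retained only when both reject.
#'
#' @param in_mask Logical cluster membership over the comparison samples.
#' @param labels Character category labels of the comparison samples.
#' @param label Target category.
#' @param alpha Significance threshold for both tests (default 0.001).
#' @return List with `p_in`, `p_out`, `retained`, `untestable`.
#' @export
categorical_association <- function(in_mask, labels, label, alpha = 0.001) {
  stopifnot(length(in_mask) == length(labels))
  p0 <- mean(labels == label)
  n_in <- sum(in_mask)
  n_out <- sum(!in_mask)
  if (p0 <= 0 || p0 >= 1 || n_in < 2L || n_out < 1L) {
    return(list(p_in = NA_real_, p_out = NA_real_, retained = FALSE,
                untestable = TRUE))
  }
  se_in <- sqrt(p0 * (1 - p0) / n_in)
  se_out <- sqrt(p0 * (1 - p0) / n_out)
  phat_in <- mean(labels[in_mask] == label)
  phat_out <- mean(labels[!in_mask] == label)
  p_in <- stats::pnorm((phat_in - p0) / se_in, lower.tail = FALSE)
  p_out <- stats::pnorm((phat_out - p0) / se_out)
  list(p_in = p_in, p_out = p_out,
       retained = is.finite(p_in) && is.finite(p_out) &&
         p_in < alpha && p_out < alpha,
       untestable = FALSE)
}

#' Quantitative context association for one cluster
#'
#' Each gene's in-cluster expression is regressed (OLS) on the covariate
#' separately; the cluster is annotated with the variable only when both
#' genes reach `R^2 > min_r2` and slope p-value `< alpha`.
#'
#' @param in_mask Logical cluster membership over the comparison samples.
#' @param values Covariate values of the comparison samples (may contain NA).
#' @param x,y The two genes' expression over the comparison samples.
#' @param alpha Slope significance threshold (default 0.001).
#' @param min_r2 Minimum per-gene R-squared (default 0.3).
#' @return List with `r2_i`, `r2_j`, `slope_p_i`, `slope_p_j`, `retained`,
#'   `untestable`.
#' @export
quantitative_association <- function(in_mask, values, x, y, alpha = 0.001,
                                     min_r2 = 0.3) {
  ok <- in_mask & !is.na(values)
  res <- list(r2_i = NA_real_, r2_j = NA_real_, slope_p_i = NA_real_,
              slope_p_j = NA_real_, retained = FALSE, untestable = TRUE)
  if (sum(ok) < 5L) return(res)
  v <- values[ok]
  if (stats::sd(v) == 0) return(res)
  fit_gene <- function(g) {
    fit <- stats::lm(g ~ v)
    sm <- summary(fit)
    p <- if (nrow(sm$coefficients) < 2L) NA_real_ else sm$coefficients[2L, 4L]
    c(r2 = sm$r.squared, p = p)
  }
  gi <- fit_gene(x[ok])
  gj <- fit_gene(y[ok])
  res$untestable <- FALSE
  res$r2_i <- gi[["r2"]]; res$r2_j <- gj[["r2"]]
  res$slope_p_i <- gi[["p"]]; res$slope_p_j <- gj[["p"]]
  res$retained <- isTRUE(gi[["r2"]] > min_r2 && gj[["r2"]] > min_r2 &&
                           is.finite(gi[["p"]]) && gi[["p"]] < alpha &&
                           is.finite(gj[["p"]]) && gj[["p"]] < alpha)
  res
}

#' Missingness-pattern similarity between two genes
#'
#' Student's (pooled-variance) two-sample t-test on the two genes' binary
#' missingness indicators over all GEM samples. In the default direction a
#' pair is kept for context annotation when the test does NOT reject
#' (p >= alpha), i.e. when the genes have statistically similar missingness
#' patterns; the alternative `"significant"` direction keeps pairs whose
#' patterns differ significantly instead.
#'
#' @param miss_i,miss_j Logical/0-1 missingness indicators, one per sample.
#' @param alpha Threshold (default 0.001).
#' @param direction `"similar"` (default) or `"significant"`.
#' @return List with `p`, `retained`.
#' @export
missingness_similarity <- function(miss_i, miss_j, alpha = 0.001,
                                   direction = c("similar", "significant")) {
  direction <- match.arg(direction)
  stopifnot(length(miss_i) == length(miss_j))
  a <- as.numeric(miss_i)
  b <- as.numeric(miss_j)
  n <- length(a)
  sp2 <- (stats::var(a) + stats::var(b)) / 2
  if (sp2 == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * 2 / n)
    p <- 2 * stats::pt(-abs(tstat), df = 2 * n - 2)
  }
  retained <- if (direction == "similar") p >= alpha else p < alpha
  list(p = p, retained = retained)
}

#' Welch differential-expression test of a cluster against its out-group
#'
#' Welch's one-way ANOVA (equivalently Welch's t-test for two groups) of one
#' gene's expression between the in-cluster samples and an out-group. Used to
#' reject context associations confounded by a covariate shared between the
#' genes: both genes of a pair must be differentially expressed between the
#' groups for the context annotation to stand.
#'
#' @param expr The gene's expression values.
#' @param in_mask Logical in-group membership (same length as `expr`).
#' @param out_mask Logical out-group membership.
#' @return The Welch p-value. Zero-variance groups of size >= 3 are handled
#'   with a variance floor of 1e-12 (with a warning).
#' @export
confound_variance_test <- function(expr, in_mask, out_mask) {
  g1 <- expr[in_mask & !is.na(expr)]
  g2 <- expr[out_mask & !is.na(expr)]
  if (length(g1) < 3L || length(g2) < 3L) {
    stop("both groups need at least 3 samples with expression")
  }
  v1 <- stats::var(g1); v2 <- stats::var(g2)
  if (v1 == 0 || v2 == 0) {
    warning("zero within-group variance; applying variance floor")
    v1 <- max(v1, 1e-12); v2 <- max(v2, 1e-12)
  }
  n1 <- length(g1); n2 <- length(g2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tstat), df = df)
}

#' Associate power-filtered clusters with experimental context
#'
#' For every cluster and every annotation variable, runs the categorical
#' (per label) or quantitative association test; each surviving association
#' is then screened by the missingness-similarity test on the pair and the
#' Welch differential-expression test on each gene. One edge record is
#' emitted per (cluster, retained context); clusters with no retained
#' context are dropped.
#'
#' @param clusters Power-filtered cluster data frame.
#' @param gem GEM matrix (defines missingness patterns and expression).
#' @param annotations Annotation table from [load_annotations()].
#' @param assoc_alpha Context-association threshold (default 0.001).
#' @param min_r2 Minimum per-gene R-squared for quantitative contexts.
#' @param miss_alpha Missingness-test threshold (default 0.001).
#' @param confound_alpha Welch-test threshold (default 0.001).
#' @param outgroup Out-group for the Welch test: `"noncluster"` (all
#'   comparison samples outside the cluster, default) or
#'   `"category-complement"` (comparison samples not carrying the target
#'   label; applies to categorical contexts, quantitative contexts fall back
#'   to the non-cluster out-group).
#' @param miss_direction Retention direction of the missingness test, see
#'   [missingness_similarity()].
#' @return Data frame of edge candidates, one row per (cluster, context),
#'   carrying all test p-values and R-squared values, with a `run_log`
#'   attribute extending the upstream counts.
#' @export
annotate_clusters <- function(clusters, gem, annotations,
                              assoc_alpha = 0.001, min_r2 = 0.3,
                              miss_alpha = 0.001, confound_alpha = 0.001,
                              outgroup = c("noncluster", "category-complement"),
                              miss_direction = c("similar", "significant")) {
  outgroup <- match.arg(outgroup)
  miss_direction <- match.arg(miss_direction)
  kinds <- variable_types(annotations)
  samples <- colnames(gem)
  stopifnot(identical(rownames(annotations), samples))
  miss_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(clusters))
  n_assoc <- 0L
  for (k in seq_len(nrow(clusters))) {
    cl <- clusters[k, ]
    codes <- strsplit(cl$samples, "")[[1L]]
    comparison <- which(codes %in% c(as.character(0:5), "7"))
    in_mask <- codes[comparison] == as.character(cl$cluster_index)
    if (sum(in_mask) < 2L) next
    gi <- cl$gene_i; gj <- cl$gene_j
    x <- gem[gi, comparison]
    y <- gem[gj, comparison]
    pair_key <- paste(gi, gj, sep = "\r")
    if (is.null(miss_cache[[pair_key]])) {
      miss_cache[[pair_key]] <- missingness_similarity(
        is.na(gem[gi, ]), is.na(gem[gj, ]),
        alpha = miss_alpha, direction = miss_direction)
    }
    miss <- miss_cache[[pair_key]]
    out <- list()
    for (v in names(kinds)) {
      if (kinds[[v]] == "categorical") {
        labs <- annotations[[v]][comparison]
        for (lab in sort(unique(labs[in_mask]))) {
          assoc <- categorical_association(in_mask, labs, lab, assoc_alpha)
          if (!assoc$retained) next
          n_assoc <- n_assoc + 1L
          out_mask <- if (outgroup == "category-complement") labs != lab
                      else !in_mask
          rec <- .bias_screen(x, y, in_mask, out_mask, miss,
                              confound_alpha)
          if (is.null(rec)) next
          out[[length(out) + 1L]] <- data.frame(
            context_kind = "categorical", variable = v, label = lab,
            p_in = assoc$p_in, p_out = assoc$p_out,
            r2_i = NA_real_, r2_j = NA_real_,
            slope_p_i = NA_real_, slope_p_j = NA_real_,
            missingness_p = miss$p,
            confound_p_i = rec[["p_i"]], confound_p_j = rec[["p_j"]],
            stringsAsFactors = FALSE)
        }
      } else {
        vals <- annotations[[v]][comparison]
        assoc <- quantitative_association(in_mask, vals, x, y,
                                          alpha = assoc_alpha,
                                          min_r2 = min_r2)
        if (!assoc$retained) next
        n_assoc <- n_assoc + 1L
        rec <- .bias_screen(x, y, in_mask, !in_mask, miss, confound_alpha)
        if (is.null(rec)) next
        out[[length(out) + 1L]] <- data.frame(
          context_kind = "quantitative", variable = v, label = NA_character_,
          p_in = NA_real_, p_out = NA_real_,
          r2_i = assoc$r2_i, r2_j = assoc$r2_j,
          slope_p_i = assoc$slope_p_i, slope_p_j = assoc$slope_p_j,
          missingness_p = miss$p,
          confound_p_i = rec[["p_i"]], confound_p_j = rec[["p_j"]],
          stringsAsFactors = FALSE)
      }
    }
    if (length(out) == 0L) next
    ctx <- do.call(rbind, out)
    base <- cl[rep(1L, nrow(ctx)),
               c("gene_i", "gene_j", "cluster_index", "num_clusters",
                 "cluster_size", "method", "r", "samples")]
    rows[[k]] <- cbind(base, ctx)
  }
  edges <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(edges)) edges <- .empty_edges()
  rownames(edges) <- NULL
  attr(edges, "run_log") <- c(attr(clusters, "run_log"),
                              context_in = nrow(clusters),
                              context_associations = n_assoc,
                              edges_out = nrow(edges))
  edges
}

# Steps 7-8 screen for one retained association; NULL when it fails.
.bias_screen <- function(x, y, in_mask, out_mask, miss, confound_alpha) {
  if (!miss$retained) return(NULL)
  if (sum(out_mask) < 3L || sum(in_mask) < 3L) return(NULL)
  p_i <- confound_variance_test(x, in_mask, out_mask)
  p_j <- confound_variance_test(y, in_mask, out_mask)
  if (!(is.finite(p_i) && is.finite(p_j) &&
        p_i < confound_alpha && p_j < confound_alpha)) return(NULL)
  c(p_i = p_i, p_j = p_j)
}

.empty_edges <- function() {
  data.frame(gene_i = character(), gene_j = character(),
             cluster_index = integer(), num_clusters = integer(),
             cluster_size = integer(), method = character(), r = numeric(),
             samples = character(), context_kind = character(),
             variable = character(), label = character(), p_in = numeric(),
             p_out = numeric(), r2_i = numeric(), r2_j = numeric(),
             slope_p_i = numeric(), slope_p_j = numeric(),
             missingness_p = numeric(), confound_p_i = numeric(),
             confound_p_j = numeric(), stringsAsFactors = FALSE)
}
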