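#' Tukey-fence outlier flags
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation (type-7 convention). Used for the pre-cluster
#' outlier pass and again inside each pairwise cluster.
#'
#' @param values Numeric vector; `NA`s are never flagged.
#' @return Logical vector of the same length; `TRUE` marks an outlier.
#' @examples
#' tukey_mask(c(1, 2, 3, 4, 5, 100))
#' @export
tukey_mask <- function(values) {
  flags <- rep(FALSE, length(values))
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    warning("fewer than 4 non-missing values; no outliers flagged")
    return(flags)
  }
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[[2L]] - q[[1L]]
  lo <- q[[1L]] - 1.5 * iqr
  hi <- q[[2L]] + 1.5 * iqr
  flags[ok] <- values[ok] < lo | values[ok] > hi
  flags
}

#' Fit a bivariate Gaussian mixture to one gene pair
#'
#' Fits full-covariance 2-D Gaussian mixtures with k = 1..`max_k` components
#' by EM (k-means++ initialization, deterministic given `seed`), selects k by
#' BIC, assigns samples by maximum posterior responsibility, and drops
#' components smaller than `min_cluster_size`. Retained clusters are
#' renumbered 0..K-1 by decreasing size (ties broken by lower mean x).
#'
#' @param x,y Paired expression values, no missing entries.
#' @param max_k Largest number of mixture components considered.
#' @param min_cluster_size Minimum samples a cluster must keep.
#' @param seed Integer-valued seed controlling the EM initialization.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per fit.
#' @return List with `K` (number of retained clusters), `labels` (integer
#'   0..K-1 per sample, `NA` for samples in no retained cluster), `bic` and
#'   `loglik` (per-k vectors, `NA` where the fit was skipped), and
#'   `selected_k` (the BIC-selected component count before size filtering).
#' @export
fit_pair_clusters <- function(x, y, max_k = 5L, min_cluster_size = 30L,
                              seed = 1L, tol = 1e-6, max_iter = 300L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < min_cluster_size) {
    return(list(K = 0L, labels = rep(NA_integer_, n),
                bic = rep(NA_real_, max_k), loglik = rep(NA_real_, max_k),
                selected_k = 0L))
  }
  fit <- cpp_gmm_pair(as.numeric(x), as.numeric(y), as.integer(max_k),
                      as.numeric(seed), tol, as.integer(max_iter))
  labels <- .filter_renumber(fit$labels, x, min_cluster_size)
  list(K = length(unique(labels[!is.na(labels)])), labels = labels,
       bic = fit$bic, loglik = fit$loglik, selected_k = fit$k)
}

# Drop components below the size floor and renumber the survivors 0..K-1
# by decreasing size, ties by lower mean x.
.filter_renumber <- function(labels, x, min_cluster_size) {
  out <- rep(NA_integer_, length(labels))
  present <- unique(labels[!is.na(labels)])
  if (length(present) == 0L) return(out)
  sizes <- vapply(present, function(l) sum(labels == l, na.rm = TRUE), 0L)
  keep <- present[sizes >= min_cluster_size]
  if (length(keep) == 0L) return(out)
  meanx <- vapply(keep, function(l) mean(x[!is.na(labels) & labels == l]), 0)
  ord <- order(-sizes[match(keep, present)], meanx)
  for (r in seq_along(ord)) {
    out[!is.na(labels) & labels == keep[ord[[r]]]] <- r - 1L
  }
  out
}

#' Remove per-cluster outliers
#'
#' Second outlier pass: within each cluster, [tukey_mask()] is applied to x
#' and y separately and flagged samples are removed from the cluster.
#' Clusters falling below `min_cluster_size` afterwards are dropped entirely.
#'
#' @param x,y Paired expression values.
#' @param labels Integer cluster labels (0-based, `NA` = unclustered) as
#'   returned by [fit_pair_clusters()].
#' @param min_cluster_size Minimum surviving cluster size.
#' @return List with `labels` (updated, renumbered 0..K-1) and `outlier`
#'   (logical; `TRUE` where a sample was removed by this pass or its whole
#'   cluster was dropped).
#' @export
remove_cluster_outliers <- function(x, y, labels, min_cluster_size = 30L) {
  outlier <- rep(FALSE, length(labels))
  new_labels <- labels
  for (l in unique(labels[!is.na(labels)])) {
    in_cl <- !is.na(labels) & labels == l
    flagged <- rep(FALSE, sum(in_cl))
    if (sum(in_cl) >= 4L) {
      flagged <- tukey_mask(x[in_cl]) | tukey_mask(y[in_cl])
    }
    idx <- which(in_cl)[flagged]
    outlier[idx] <- TRUE
    new_labels[idx] <- NA_integer_
  }
  kept <- .filter_renumber(new_labels, x, min_cluster_size)
  # samples whose cluster was dropped by the size floor count as removed
  outlier[!is.na(new_labels) & is.na(kept)] <- TRUE
  list(labels = kept, outlier = outlier)
}

#' Per-cluster correlation
#'
#' @param x,y Paired expression values.
#' @param labels Integer cluster labels (0-based, `NA` = unclustered).
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame with one row per cluster that has at least 3 samples
#'   and non-zero variance in both genes: `cluster` (label), `size`, `r`.
#'   Degenerate clusters are excluded.
#' @export
cluster_correlation <- function(x, y, labels, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  labs <- sort(unique(labels[!is.na(labels)]))
  rows <- lapply(labs, function(l) {
    in_cl <- !is.na(labels) & labels == l
    if (sum(in_cl) < 3L) return(NULL)
    xs <- x[in_cl]; ys <- y[in_cl]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NULL)
    data.frame(cluster = l, size = sum(in_cl),
               r = stats::cor(xs, ys, method = method))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cluster = integer(), size = integer(),
                                      r = numeric())
  out
}

#' Pairwise similarity pass over all gene pairs
#'
#' Runs the per-pair workflow over every gene pair i < j (by GEM row order):
#' drop samples missing in either gene (state code `'9'`), remove Tukey
#' outliers on each gene's pairwise-complete values (`'6'`), cluster the
#' remaining scatter with a Gaussian mixture, remove per-cluster outliers
#' (`'7'`), and score each surviving cluster by correlation. Clusters with
#' `|r|` below `min_abs_correlation` are discarded. Samples whose cluster was
#' dropped at or after the clustering stage (undersized, zero-variance, or
#' below the correlation floor) also carry code `'7'`; digits `0..5` mark
#' membership in an emitted cluster.
#'
#' @param gem GEM matrix from [load_gem()].
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @param max_k Maximum mixture components per pair.
#' @param min_cluster_size Minimum cluster size.
#' @param min_abs_correlation Minimum `|r|` for a cluster to be emitted
#'   (default 0.5).
#' @param seed Integer seed; per-pair seeds are derived deterministically.
#' @param tol,max_iter EM controls, see [fit_pair_clusters()].
#' @return Data frame with one row per emitted cluster: `gene_i`, `gene_j`,
#'   `cluster_index`, `num_clusters`, `cluster_size`, `method`, `r`,
#'   `samples` (the per-pair sample state string). A `run_log` attribute
#'   counts pairs examined, skipped and emitted.
#' @export
similarity_pass <- function(gem, method = c("pearson", "spearman"),
                            max_k = 5L, min_cluster_size = 30L,
                            min_abs_correlation = 0.5, seed = 1L,
                            tol = 1e-6, max_iter = 300L) {
  method <- match.arg(method)
  genes <- rownames(gem)
  ng <- length(genes)
  n <- ncol(gem)
  rows <- vector("list", 1024L)
  nrows <- 0L
  n_pairs <- 0L
  n_skipped <- 0L
  n_emitted_pairs <- 0L
  for (i in seq_len(max(ng - 1L, 0L))) {
    xi <- gem[i, ]
    for (j in seq.int(i + 1L, ng)) {
      n_pairs <- n_pairs + 1L
      yj <- gem[j, ]
      pair_seed <- .pair_seed(seed, i, j, ng)
      res <- .process_pair(xi, yj, method, max_k, min_cluster_size,
                           min_abs_correlation, pair_seed, tol, max_iter)
      if (is.null(res)) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (nrow(res) == 0L) next
      res$gene_i <- genes[[i]]
      res$gene_j <- genes[[j]]
      n_emitted_pairs <- n_emitted_pairs + 1L
      nrows <- nrows + 1L
      if (nrows > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nrows]] <- res
    }
  }
  out <- do.call(rbind, rows[seq_len(nrows)])
  if (is.null(out)) {
    out <- data.frame(gene_i = character(), gene_j = character(),
                      cluster_index = integer(), num_clusters = integer(),
                      cluster_size = integer(), method = character(),
                      r = numeric(), samples = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[, c("gene_i", "gene_j", "cluster_index", "num_clusters",
                   "cluster_size", "method", "r", "samples")]
    rownames(out) <- NULL
  }
  attr(out, "run_log") <- c(pairs_examined = n_pairs,
                            pairs_skipped = n_skipped,
                            pairs_emitted = n_emitted_pairs,
                            clusters_emitted = nrow(out))
  out
}

.pair_seed <- function(seed, i, j, ng) {
  # deterministic per-pair seed, independent of execution order
  (as.numeric(seed) %% 2^31) * 2^20 + (i - 1) * ng + j
}

# One pair through Steps 1-4. Returns NULL when the pair lacks enough
# complete samples, else a data frame of emitted clusters (possibly empty).
.process_pair <- function(x, y, method, max_k, min_cluster_size,
                          min_abs_correlation, pair_seed, tol, max_iter) {
  n <- length(x)
  codes <- rep("9", n)
  complete <- !is.na(x) & !is.na(y)
  if (sum(complete) < min_cluster_size) return(NULL)
  idx <- which(complete)
  xs <- x[idx]; ys <- y[idx]
  out1 <- tukey_mask(xs) | tukey_mask(ys)
  codes[idx[out1]] <- "6"
  keep <- idx[!out1]
  codes[keep] <- "7"  # provisional: refined to digits below
  xs <- x[keep]; ys <- y[keep]
  if (length(keep) < min_cluster_size) {
    return(.emit_clusters(NULL, codes, method))
  }
  fit <- fit_pair_clusters(xs, ys, max_k = max_k,
                           min_cluster_size = min_cluster_size,
                           seed = pair_seed, tol = tol, max_iter = max_iter)
  cl3 <- remove_cluster_outliers(xs, ys, fit$labels,
                                 min_cluster_size = min_cluster_size)
  cors <- cluster_correlation(xs, ys, cl3$labels, method = method)
  cors <- cors[abs(cors$r) >= min_abs_correlation, , drop = FALSE]
  # renumber emitted clusters 0..K-1 by decreasing size, ties by mean x
  if (nrow(cors) > 0L) {
    meanx <- vapply(cors$cluster, function(l) {
      mean(xs[!is.na(cl3$labels) & cl3$labels == l])
    }, 0)
    ord <- order(-cors$size, meanx)
    cors <- cors[ord, , drop = FALSE]
    for (new_idx in seq_len(nrow(cors))) {
      old <- cors$cluster[[new_idx]]
      codes[keep[!is.na(cl3$labels) & cl3$labels == old]] <-
        as.character(new_idx - 1L)
    }
    cors$cluster <- seq_len(nrow(cors)) - 1L
  }
  .emit_clusters(cors, codes, method)
}

.emit_clusters <- function(cors, codes, method) {
  state <- paste(codes, collapse = "")
  if (is.null(cors) || nrow(cors) == 0L) {
    return(data.frame(cluster_index = integer(), num_clusters = integer(),
                      cluster_size = integer(), method = character(),
                      r = numeric(), samples = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(cluster_index = cors$cluster, num_clusters = nrow(cors),
             cluster_size = cors$size, method = method, r = cors$r,
             samples = state, stringsAsFactors = FALSE)
}

#' Write / read a cluster table
#'
#' The tab-delimited cluster file produced by [similarity_pass()]; one row
#' per retained cluster. This file is the input to the power filter.
#'
#' @param clusters Cluster data frame.
#' @param path File path.
#' @return `write_clusters` returns `path` invisibly; `read_clusters`
#'   returns the data frame.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c(samples = "character"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
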