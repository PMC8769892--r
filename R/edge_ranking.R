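#' Rank context-specific edges
#'
#' Assigns each edge a composite valuation score combining its correlation
#' magnitude, the strength of its context association and (for quantitative
#' contexts) the mean per-gene R-squared:
#' \deqn{score = |r| \times \min(-\log_{10} p_{ctx}, 20)/20 \times q}
#' where `p_ctx` is the worst (largest) context p-value of the record and
#' `q` is the mean per-gene R-squared for quantitative contexts and 1 for
#' categorical ones. The composite form is this package's own valuation
#' choice; the cap at 20 keeps scores finite when a p-value underflows to 0.
#' Edges are sorted by decreasing score; exact ties fall back to the
#' lexicographic key (gene_i, gene_j, cluster_index, context).
#'
#' @param edges Edge data frame from [annotate_clusters()].
#' @return The same records ordered by rank, with `rank_score` and `rank`
#'   (1..n) columns appended.
#' @export
rank_edges <- function(edges) {
  if (nrow(edges) == 0L) {
    edges$rank_score <- numeric(0)
    edges$rank <- integer(0)
    return(edges)
  }
  p_ctx <- ifelse(edges$context_kind == "categorical",
                  pmax(edges$p_in, edges$p_out),
                  pmax(edges$slope_p_i, edges$slope_p_j))
  q <- ifelse(edges$context_kind == "categorical", 1,
              (edges$r2_i + edges$r2_j) / 2)
  logp <- pmin(-log10(p_ctx), 20)
  logp[p_ctx <= 0] <- 20
  score <- abs(edges$r) * logp / 20 * q
  context <- ifelse(is.na(edges$label), edges$variable,
                    paste(edges$variable, edges$label, sep = "="))
  ord <- order(-score, edges$gene_i, edges$gene_j, edges$cluster_index,
               context, method = "radix")
  out <- edges[ord, , drop = FALSE]
  out$rank_score <- score[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "run_log") <- attr(edges, "run_log")
  out
}

.network_columns <- c("gene_i", "gene_j", "cluster_index", "num_clusters",
                      "cluster_size", "method", "r", "samples",
                      "context_kind", "variable", "label", "p_in", "p_out",
                      "r2_i", "r2_j", "slope_p_i", "slope_p_j",
                      "missingness_p", "confound_p_i", "confound_p_j",
                      "rank_score", "rank")

#' Write a csGCN edge table
#'
#' `"full-tsv"` writes every edge field in a fixed column order (the format
#' [read_network()] reads back); `"minimal-tsv"` writes a 4-column
#' Cytoscape-loadable edge table (source, target, score, context).
#'
#' @param edges Ranked edge data frame from [rank_edges()].
#' @param path Output path.
#' @param format `"full-tsv"` (default) or `"minimal-tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("full-tsv", "minimal-tsv")) {
  format <- match.arg(format)
  if (format == "minimal-tsv") {
    out <- data.frame(source = edges$gene_i, target = edges$gene_j,
                      score = edges$rank_score,
                      context = ifelse(is.na(edges$label), edges$variable,
                                       paste(edges$variable, edges$label,
                                             sep = "=")),
                      stringsAsFactors = FALSE)
  } else {
    extra <- setdiff(colnames(edges), .network_columns)
    out <- edges[, c(.network_columns, extra), drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a full-tsv csGCN edge table
#'
#' Inverse of [write_network()] for the `"full-tsv"` format. Unknown extra
#' columns are preserved; a missing required column is an error naming it.
#'
#' @param path Path to a full-tsv network file.
#' @return Edge data frame.
#' @export
read_network <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(.network_columns, colnames(tab))
  if (length(missing_cols) > 0L) {
    stop("network file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  int_cols <- c("cluster_index", "num_clusters", "cluster_size", "rank")
  num_cols <- c("r", "p_in", "p_out", "r2_i", "r2_j", "slope_p_i",
                "slope_p_j", "missingness_p", "confound_p_i", "confound_p_j",
                "rank_score")
  for (cn in int_cols) tab[[cn]] <- as.integer(tab[[cn]])
  for (cn in num_cols) tab[[cn]] <- as.numeric(tab[[cn]])
  tab
}
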