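#' Configuration for the synthetic csGCN benchmark
#'
#' Describes a multi-condition expression experiment with planted
#' context-specific co-expression. The default scenario emulates a
#' multi-genotype, multi-treatment time-course design: 300 samples over
#' 4 genotypes x 5 treatments (15 samples per combination) with a 0-8 h
#' time covariate, expression on a log scale around a base level of 5, and
#' 20 planted gene pairs per archetype:
#'
#' * `bimodal_split` - within one genotype the pair is strongly correlated
#'   (rho 0.8) around a mean shifted 4 noise-sd away; the remaining
#'   genotypes sit uncorrelated at the base level, giving two distinct modes
#'   of co-expression split by the category.
#' * `category_specific` - correlation (rho 0.9) exists only inside one
#'   treatment, whose samples are up-regulated in both genes (+2.8 noise-sd)
#'   with a tighter within-condition dispersion (0.7 noise-sd), so the two
#'   groups' tails still overlap; elsewhere the genes are independent. The
#'   shift reflects that condition-specific co-expression typically comes
#'   with condition-specific expression level (the confound screen's
#'   differential-expression requirement also presumes it), and the compact
#'   dispersion keeps a 20%-minority condition cluster from being clipped
#'   by the pooled Tukey fences.
#' * `confounded` - gene A depends linearly on time in every sample, while
#'   gene B responds to time only inside the heat treatment (plus an offset);
#'   the within-heat correlation is real but driven by the shared covariate,
#'   the archetype the confound screen must reject.
#' * `basal_pair` - both genes track time everywhere (ubiquitous,
#'   clock-like expression).
#' * `null` - independent noise.
#'
#' @param n_samples Total samples (must be divisible by the number of
#'   genotype x treatment combinations).
#' @param genotypes,treatments Category labels.
#' @param time_grid Values of the quantitative time covariate, assigned
#'   cyclically across samples.
#' @param archetype_counts Named integer vector of planted pairs per
#'   archetype.
#' @param spoke_triples Number of planted missingness "spoke" triples: two
#'   genes expressed (observed) only inside one treatment plus one
#'   ubiquitous partner sharing their latent signal. Used to exercise the
#'   missingness-similarity screen; default 0.
#' @param noise_sd Residual (noise) standard deviation on the log scale.
#' @param base Baseline log-expression level.
#' @param rho_bimodal,rho_category Within-category generating correlations.
#' @param beta_time Time slope of time-dependent genes.
#' @param missing_rate Uniform per-cell missingness probability.
#' @param n_genes Total genes; defaults to exactly the planted genes. Extra
#'   genes are filled with independent noise.
#' @param seed Integer seed making generation deterministic.
#' @return A `list` of class `csgcn_config`.
#' @export
synthetic_config <- function(n_samples = 300L,
                             genotypes = paste0("G", 1:4),
                             treatments = c("control", "heat",
                                            "heat_recovery", "drought",
                                            "drought_recovery"),
                             time_grid = seq(0, 8, by = 0.5),
                             archetype_counts = c(bimodal_split = 20L,
                                                  category_specific = 20L,
                                                  confounded = 20L,
                                                  basal_pair = 20L,
                                                  null = 20L),
                             spoke_triples = 0L,
                             noise_sd = 0.5, base = 5,
                             rho_bimodal = 0.8, rho_category = 0.9,
                             beta_time = 0.3,
                             missing_rate = 0.01,
                             n_genes = NULL, seed = 1L) {
  n_combo <- length(genotypes) * length(treatments)
  if (n_samples %% n_combo != 0L) {
    stop("n_samples must be divisible by the ", n_combo,
         " genotype x treatment combinations")
  }
  stopifnot(noise_sd > 0, missing_rate >= 0, missing_rate <= 1,
            all(archetype_counts >= 0))
  needed <- 2L * sum(archetype_counts) + 3L * spoke_triples
  if (is.null(n_genes)) n_genes <- needed
  if (n_genes < needed) {
    stop("config plants ", needed, " genes but n_genes = ", n_genes)
  }
  cfg <- list(n_samples = as.integer(n_samples), genotypes = genotypes,
              treatments = treatments, time_grid = time_grid,
              archetype_counts = archetype_counts,
              spoke_triples = as.integer(spoke_triples),
              noise_sd = noise_sd, base = base,
              rho_bimodal = rho_bimodal, rho_category = rho_category,
              beta_time = beta_time, missing_rate = missing_rate,
              n_genes = as.integer(n_genes), seed = as.integer(seed))
  class(cfg) <- "csgcn_config"
  cfg
}

# correlated standard-normal pair with correlation rho, scaled by sd
.bvn <- function(n, rho, sd = 1) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2) * sd
}

#' Generate a synthetic GEM with planted context-specific structure
#'
#' @param config A [synthetic_config()].
#' @return List with `gem` (matrix), `annotations` (data frame with
#'   `genotype`, `treatment` categorical and `time` quantitative), and
#'   `truth` (data frame: `gene_i`, `gene_j`, `archetype`, `variable`,
#'   `label`, `rho` - the expected pipeline context per planted pair; for
#'   confounded pairs the recorded category context is the association the
#'   pipeline is expected to reject).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- config$n_samples
  per_combo <- n / (length(config$genotypes) * length(config$treatments))
  genotype <- rep(config$genotypes, each = per_combo * length(config$treatments))
  treatment <- rep(rep(config$treatments, each = per_combo),
                   times = length(config$genotypes))
  time <- rep(config$time_grid, length.out = n)
  sample_ids <- sprintf("S%03d", seq_len(n))
  sd <- config$noise_sd
  base <- config$base
  vt <- stats::var(time)

  gene_rows <- list()
  truth_rows <- list()
  gid <- 0L
  next_gene <- function() {
    gid <<- gid + 1L
    sprintf("g%04d", gid)
  }
  add_pair <- function(x, y, archetype, variable, label, rho) {
    gi <- next_gene(); gj <- next_gene()
    gene_rows[[gi]] <<- x
    gene_rows[[gj]] <<- y
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      gene_i = gi, gene_j = gj, archetype = archetype,
      variable = variable, label = label, rho = rho,
      stringsAsFactors = FALSE)
  }

  counts <- config$archetype_counts
  for (p in seq_len(counts[["bimodal_split"]])) {
    g <- config$genotypes[[(p - 1L) %% length(config$genotypes) + 1L]]
    in_cat <- genotype == g
    x <- base + stats::rnorm(n, sd = sd)
    y <- base + stats::rnorm(n, sd = sd)
    b <- .bvn(sum(in_cat), config$rho_bimodal, sd)
    x[in_cat] <- base + 4 * sd + b[, 1L]
    y[in_cat] <- base + 4 * sd + b[, 2L]
    add_pair(x, y, "bimodal_split", "genotype", g, config$rho_bimodal)
  }
  for (p in seq_len(counts[["category_specific"]])) {
    tr <- config$treatments[[(p - 1L) %% length(config$treatments) + 1L]]
    in_cat <- treatment == tr
    x <- base + stats::rnorm(n, sd = sd)
    y <- base + stats::rnorm(n, sd = sd)
    b <- .bvn(sum(in_cat), config$rho_category, 0.7 * sd)
    x[in_cat] <- base + 2.8 * sd + b[, 1L]
    y[in_cat] <- base + 2.8 * sd + b[, 2L]
    add_pair(x, y, "category_specific", "treatment", tr,
             config$rho_category)
  }
  beta <- config$beta_time
  for (p in seq_len(counts[["confounded"]])) {
    in_cat <- treatment == "heat"
    x <- base + beta * time + stats::rnorm(n, sd = sd)
    y <- base + stats::rnorm(n, sd = sd)
    y[in_cat] <- base + 4 * sd - beta * time[in_cat] +
      stats::rnorm(sum(in_cat), sd = sd)
    rho <- -beta^2 * vt / (beta^2 * vt + sd^2)
    add_pair(x, y, "confounded", "treatment", "heat", rho)
  }
  for (p in seq_len(counts[["basal_pair"]])) {
    x <- base + beta * time + stats::rnorm(n, sd = sd)
    y <- base + beta * time + stats::rnorm(n, sd = sd)
    rho <- beta^2 * vt / (beta^2 * vt + sd^2)
    add_pair(x, y, "basal_pair", "time", NA_character_, rho)
  }
  for (p in seq_len(counts[["null"]])) {
    add_pair(base + stats::rnorm(n, sd = sd), base + stats::rnorm(n, sd = sd),
             "null", NA_character_, NA_character_, 0)
  }
  for (p in seq_len(config$spoke_triples)) {
    tr <- config$treatments[[(p - 1L) %% length(config$treatments) + 1L]]
    in_cat <- treatment == tr
    z <- stats::rnorm(n)
    eps_sd <- sqrt(1 / config$rho_category - 1)
    mk <- function() base + z + stats::rnorm(n, sd = eps_sd)
    x <- mk(); y <- mk(); zgene <- mk()
    x[!in_cat] <- NA_real_
    y[!in_cat] <- NA_real_
    gx <- next_gene(); gy <- next_gene(); gz <- next_gene()
    gene_rows[[gx]] <- x; gene_rows[[gy]] <- y; gene_rows[[gz]] <- zgene
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      gene_i = c(gx, gx), gene_j = c(gy, gz),
      archetype = c("spoke_pair", "spoke_mixed"),
      variable = "treatment", label = tr, rho = config$rho_category,
      stringsAsFactors = FALSE)
  }
  while (gid < config$n_genes) {
    gene_rows[[next_gene()]] <- base + stats::rnorm(n, sd = sd)
  }

  gem <- do.call(rbind, gene_rows)
  rownames(gem) <- names(gene_rows)
  colnames(gem) <- sample_ids
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(gem)) < config$missing_rate,
                   nrow = nrow(gem))
    gem[drop] <- NA_real_
  }
  annotations <- data.frame(genotype = genotype, treatment = treatment,
                            time = time, stringsAsFactors = FALSE)
  rownames(annotations) <- sample_ids
  attr(annotations, "variable_types") <- c(genotype = "categorical",
                                           treatment = "categorical",
                                           time = "quantitative")
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(gem = gem, annotations = annotations, truth = truth)
}

#' Score network recovery against the planted truth
#'
#' A planted pair is recovered when the network contains an edge for that
#' pair annotated with its true context (matching variable and, for
#' categorical contexts, label).
#'
#' @param truth Truth table from [generate_dataset()].
#' @param network Ranked edge data frame.
#' @return Data frame with one row per archetype: `n_pairs`, `n_edges`
#'   (edges on the archetype's pairs), `n_correct` (edges carrying the true
#'   context), `recall`, `precision` (1 with `zero_denominator = TRUE` when
#'   the archetype has no edges), and `edge_rate` (fraction of the
#'   archetype's pairs with at least one edge of any context).
#' @export
score_recovery <- function(truth, network) {
  pair_key <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  }
  net_key <- pair_key(network$gene_i, network$gene_j)
  rows <- lapply(split(truth, truth$archetype), function(tt) {
    keys <- pair_key(tt$gene_i, tt$gene_j)
    on_pairs <- network[net_key %in% keys, , drop = FALSE]
    correct <- logical(nrow(tt))
    for (i in seq_len(nrow(tt))) {
      if (is.na(tt$variable[[i]])) next
      hit <- net_key %in% keys[[i]] & network$variable == tt$variable[[i]]
      if (!is.na(tt$label[[i]])) {
        hit <- hit & !is.na(network$label) & network$label == tt$label[[i]]
      }
      correct[[i]] <- any(hit)
    }
    n_correct_edges <- sum(
      paste(net_key[net_key %in% keys], on_pairs$variable,
            ifelse(is.na(on_pairs$label), "", on_pairs$label)) %in%
        paste(keys[!is.na(tt$variable)], tt$variable[!is.na(tt$variable)],
              ifelse(is.na(tt$label[!is.na(tt$variable)]), "",
                     tt$label[!is.na(tt$variable)])))
    data.frame(
      archetype = tt$archetype[[1L]], n_pairs = nrow(tt),
      n_edges = nrow(on_pairs), n_correct = n_correct_edges,
      recall = if (all(is.na(tt$variable))) NA_real_ else
        mean(correct[!is.na(tt$variable)]),
      precision = if (nrow(on_pairs) == 0L) 1 else
        n_correct_edges / nrow(on_pairs),
      zero_denominator = nrow(on_pairs) == 0L,
      edge_rate = mean(keys %in% net_key),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
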