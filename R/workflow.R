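#' Pipeline configuration
#'
#' Collects the paths and parameters of the full csGCN workflow. Defaults
#' are the workflow's standard operating point: minimum cluster correlation
#' magnitude 0.5, power 0.8 at alpha 0.001 for the correlation power filter,
#' context-association alpha 0.001 with minimum R-squared 0.3, missingness
#' and confound alphas 0.001, audit alpha 0.01.
#'
#' @param gem Path to the GEM file.
#' @param annotations Path to the annotation file.
#' @param out_prefix Output path prefix for the network files and run log.
#' @param quantitative Names of annotation variables to parse as
#'   quantitative covariates (all others are categorical).
#' @param method Correlation method.
#' @param max_k,min_cluster_size,min_abs_correlation Pairwise-engine
#'   parameters, see [similarity_pass()].
#' @param power,alpha Power-filter parameters, see
#'   [min_samples_for_correlation()].
#' @param assoc_alpha,min_r2,miss_alpha,confound_alpha,outgroup,miss_direction
#'   Context-test parameters, see [annotate_clusters()].
#' @param audit_alpha Assumption-audit significance level.
#' @param seed Integer seed for the whole run.
#' @return A list of class `csgcn_pipeline_config`.
#' @export
pipeline_config <- function(gem, annotations, out_prefix,
                            quantitative = character(),
                            method = "pearson", max_k = 5L,
                            min_cluster_size = 30L,
                            min_abs_correlation = 0.5,
                            power = 0.8, alpha = 0.001,
                            assoc_alpha = 0.001, min_r2 = 0.3,
                            miss_alpha = 0.001, confound_alpha = 0.001,
                            outgroup = "noncluster",
                            miss_direction = "similar",
                            audit_alpha = 0.01, seed = 1L) {
  cfg <- list(gem = gem, annotations = annotations, out_prefix = out_prefix,
              quantitative = quantitative, method = method,
              max_k = as.integer(max_k),
              min_cluster_size = as.integer(min_cluster_size),
              min_abs_correlation = min_abs_correlation, power = power,
              alpha = alpha, assoc_alpha = assoc_alpha, min_r2 = min_r2,
              miss_alpha = miss_alpha, confound_alpha = confound_alpha,
              outgroup = outgroup, miss_direction = miss_direction,
              audit_alpha = audit_alpha, seed = as.integer(seed))
  class(cfg) <- "csgcn_pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config Configuration from [pipeline_config()].
#' @return `read_pipeline_config` returns the configuration;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("gem", "annotations", "out_prefix")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("pipeline config is missing field(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(raw$quantitative)) {
    raw$quantitative <- as.character(raw$quantitative)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the csGCN construction workflow end to end
#'
#' Executes the stages in order: pairwise similarity pass (outlier removal,
#' mixture clustering, cluster outlier removal, correlation), correlation
#' power filter, context association with missingness and confound
#' screening, and edge ranking. Writes `<out_prefix>.network.tsv` (full
#' edge table), `<out_prefix>.cytoscape.tsv` (minimal edge table) and
#' `<out_prefix>.log.tsv` (per-stage counts).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `network` (ranked edge data frame),
#'   `clusters` (similarity-pass output) and `run_log` (named counts).
#' @export
run_pipeline <- function(config) {
  stage <- "load inputs"
  result <- tryCatch({
    gem <- load_gem(config$gem)
    types <- stats::setNames(rep("quantitative",
                                 length(config$quantitative)),
                             config$quantitative)
    ann <- load_annotations(config$annotations, gem, declared_types = types)

    stage <- "similarity pass"
    clusters <- similarity_pass(gem, method = config$method,
                                max_k = config$max_k,
                                min_cluster_size = config$min_cluster_size,
                                min_abs_correlation = config$min_abs_correlation,
                                seed = config$seed)

    stage <- "power filter"
    filtered <- apply_power_filter(clusters, alpha = config$alpha,
                                   power = config$power)

    stage <- "context tests"
    edges <- annotate_clusters(filtered, gem, ann,
                               assoc_alpha = config$assoc_alpha,
                               min_r2 = config$min_r2,
                               miss_alpha = config$miss_alpha,
                               confound_alpha = config$confound_alpha,
                               outgroup = config$outgroup,
                               miss_direction = config$miss_direction)

    stage <- "edge ranking"
    ranked <- rank_edges(edges)

    stage <- "write outputs"
    write_network(ranked, paste0(config$out_prefix, ".network.tsv"))
    write_network(ranked, paste0(config$out_prefix, ".cytoscape.tsv"),
                  format = "minimal-tsv")
    run_log <- attr(ranked, "run_log")
    log_df <- data.frame(stage = names(run_log), count = unname(run_log))
    utils::write.table(log_df, paste0(config$out_prefix, ".log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(network = ranked, clusters = clusters, run_log = run_log)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
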