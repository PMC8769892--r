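# A reduced planted scenario (2 pairs per archetype, 300 samples) shared by
# the integration tests; generated once per test run.
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        archetype_counts = c(bimodal_split = 2L, category_specific = 2L,
                             confounded = 2L, basal_pair = 2L, null = 2L),
        seed = 7L)
      ds <- generate_dataset(cfg)
      clusters <- similarity_pass(ds$gem, seed = 7L)
      filtered <- apply_power_filter(clusters)
      network <- rank_edges(annotate_clusters(filtered, ds$gem,
                                              ds$annotations))
      cache <<- list(config = cfg, data = ds, clusters = clusters,
                     filtered = filtered, network = network)
    }
    cache
  }
})
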