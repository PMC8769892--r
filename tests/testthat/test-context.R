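test_that("a perfectly condition-aligned cluster is strongly associated", {
  labels <- rep(c("heat", "control", "drought", "cold"), each = 25)
  in_mask <- labels == "heat"
  res <- categorical_association(in_mask, labels, "heat")
  expect_lt(res$p_in, 1e-6)
  expect_lt(res$p_out, 1e-6)
  expect_true(res$retained)
  # cross-check against the chi-square form of the proportion test
  p0 <- mean(labels == "heat")
  alt_in <- stats::prop.test(sum(labels[in_mask] == "heat"), sum(in_mask),
                             p = p0, alternative = "greater",
                             correct = FALSE)$p.value
  expect_equal(res$p_in, alt_in, tolerance = 1e-10)
  alt_out <- stats::prop.test(sum(labels[!in_mask] == "heat"), sum(!in_mask),
                              p = p0, alternative = "less",
                              correct = FALSE)$p.value
  expect_equal(res$p_out, alt_out, tolerance = 1e-10)
})

test_that("degenerate prevalence makes the association untestable", {
  labels <- rep("heat", 50)
  res <- categorical_association(rep(TRUE, 50), labels, "heat")
  expect_true(res$untestable)
  expect_false(res$retained)
  # label absent from the comparison set
  res2 <- categorical_association(rep(c(TRUE, FALSE), 25),
                                  rep("control", 50), "heat")
  expect_true(res2$untestable)
})

test_that("null categorical associations are retained at about the alpha rate", {
  set.seed(501)
  alpha <- 0.05
  hits_in <- 0L
  reps <- 1000L
  labels <- rep(c("heat", "other"), c(50, 150))
  for (i in seq_len(reps)) {
    in_mask <- seq_along(labels) %in% sample(200, 60)
    res <- categorical_association(in_mask, labels, "heat", alpha = alpha)
    if (!res$untestable && res$p_in < alpha) hits_in <- hits_in + 1L
  }
  band <- 3 * sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(hits_in / reps - alpha), band + 0.01)
})

test_that("quantitative association requires both genes to track the covariate", {
  tvals <- rep(seq(0, 8, 0.5), length.out = 60)
  in_mask <- rep(TRUE, 60)
  x <- 1 + 2 * tvals
  y <- 3 - 0.5 * tvals
  res <- suppressWarnings(quantitative_association(in_mask, tvals, x, y))
  expect_equal(res$r2_i, 1)
  expect_equal(res$r2_j, 1)
  expect_true(res$retained)
  # constant covariate: untestable
  res2 <- quantitative_association(in_mask, rep(2, 60), x, y)
  expect_true(res2$untestable)
  # one gene independent of the covariate: fails the both-genes rule
  set.seed(502)
  res3 <- suppressWarnings(quantitative_association(in_mask, tvals, x, rnorm(60)))
  expect_false(res3$retained)
  expect_lt(res3$r2_j, 0.3)
  # oracle: per-gene R^2 and slope p from stats::lm directly
  noisy <- x + rnorm(60, sd = 0.5)
  res4 <- suppressWarnings(quantitative_association(in_mask, tvals, noisy, y))
  sm <- summary(stats::lm(noisy ~ tvals))
  expect_equal(res4$r2_i, sm$r.squared, tolerance = 1e-12)
  expect_equal(res4$slope_p_i, sm$coefficients[2, 4], tolerance = 1e-12)
})

test_that("missingness screen keeps similar patterns, rejects spokes", {
  # identical patterns: trivially similar
  m <- rep(c(TRUE, FALSE), c(10, 90))
  expect_equal(missingness_similarity(m, m)$p, 1)
  expect_true(missingness_similarity(m, m)$retained)
  # fully observed pair: retained
  none <- rep(FALSE, 100)
  expect_true(missingness_similarity(none, none)$retained)
  # spoke case: one gene missing in 80/100 samples, partner in none
  spoke_i <- rep(c(TRUE, FALSE), c(80, 20))
  res <- missingness_similarity(spoke_i, none)
  expect_lt(res$p, 0.001)
  expect_false(res$retained)
  # oracle: pooled-variance t-test on the indicator vectors
  tt <- stats::t.test(as.numeric(spoke_i), as.numeric(none),
                      var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # reversed retention direction
  expect_true(missingness_similarity(spoke_i, none,
                                     direction = "significant")$retained)
})

test_that("missingness t-test is calibrated under a shared missingness rate", {
  set.seed(503)
  alpha <- 0.05
  reps <- 1000L
  hits <- 0L
  for (i in seq_len(reps)) {
    a <- runif(150) < 0.3
    b <- runif(150) < 0.3
    if (missingness_similarity(a, b, alpha = alpha)$p < alpha) {
      hits <- hits + 1L
    }
  }
  band <- 3 * sqrt(alpha * (1 - alpha) / reps)
  # t on Bernoulli indicators is approximate; allow a small discreteness slack
  expect_lt(abs(hits / reps - alpha), band + 0.015)
})

test_that("Welch screen detects differential expression and matches t.test", {
  set.seed(504)
  expr <- c(rnorm(60, 10), rnorm(200, 5))
  in_mask <- rep(c(TRUE, FALSE), c(60, 200))
  p <- confound_variance_test(expr, in_mask, !in_mask)
  expect_lt(p, 1e-6)
  tt <- stats::t.test(expr[in_mask], expr[!in_mask])
  expect_equal(p, tt$p.value, tolerance = 1e-10)
  # identically distributed groups: typically not significant
  expr0 <- rnorm(260)
  expect_gt(confound_variance_test(expr0, in_mask, !in_mask), 0.001)
  # empty out-group violates the precondition
  expect_error(confound_variance_test(expr, in_mask, rep(FALSE, 260)),
               "at least 3")
  # zero-variance group: variance floor with warning
  expr_c <- c(rep(5, 60), rnorm(200))
  expect_warning(pf <- confound_variance_test(expr_c, in_mask, !in_mask),
                 "variance floor")
  expect_true(is.finite(pf))
})

test_that("Welch screen is calibrated under the null", {
  set.seed(505)
  alpha <- 0.05
  reps <- 1000L
  in_mask <- rep(c(TRUE, FALSE), each = 100)
  hits <- 0L
  for (i in seq_len(reps)) {
    expr <- rnorm(200)
    if (confound_variance_test(expr, in_mask, !in_mask) < alpha) {
      hits <- hits + 1L
    }
  }
  band <- 3 * sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(hits / reps - alpha), band)
})

test_that("cluster annotation recovers planted contexts and drops confounds", {
  sc <- small_scenario()
  net <- sc$network
  truth <- sc$data$truth
  # every bimodal/category pair appears with its true context
  planted <- truth[truth$archetype %in% c("bimodal_split",
                                          "category_specific"), ]
  for (i in seq_len(nrow(planted))) {
    hit <- net$gene_i == planted$gene_i[i] &
      net$gene_j == planted$gene_j[i] &
      net$variable == planted$variable[i] &
      !is.na(net$label) & net$label == planted$label[i]
    expect_true(any(hit),
                label = paste("recovered", planted$gene_i[i],
                              planted$gene_j[i], planted$label[i]))
  }
  # confounded pairs contribute no categorical edges
  conf <- truth[truth$archetype == "confounded", ]
  conf_edges <- net[paste(net$gene_i, net$gene_j) %in%
                      paste(conf$gene_i, conf$gene_j) &
                      net$context_kind == "categorical", ]
  expect_identical(nrow(conf_edges), 0L)
  # all emitted records satisfy their stated thresholds
  cat_e <- net[net$context_kind == "categorical", ]
  expect_true(all(cat_e$p_in < 0.001 & cat_e$p_out < 0.001))
  expect_true(all(net$missingness_p >= 0.001))
  expect_true(all(net$confound_p_i < 0.001 & net$confound_p_j < 0.001))
})

test_that("a cluster spanning all samples with no structure yields no edge", {
  set.seed(506)
  n <- 120
  b <- rbvn(n, 0.8, sd = 0.5, mean = 5)
  gem <- rbind(gx = b[, 1], gy = b[, 2])
  colnames(gem) <- sprintf("S%03d", 1:n)
  ann <- data.frame(treatment = rep(c("a", "b"), each = n / 2),
                    stringsAsFactors = FALSE)
  rownames(ann) <- colnames(gem)
  attr(ann, "variable_types") <- c(treatment = "categorical")
  cl <- apply_power_filter(similarity_pass(gem, seed = 3))
  expect_gte(nrow(cl), 1L)
  edges <- annotate_clusters(cl, gem, ann)
  expect_identical(nrow(edges), 0L)
})
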