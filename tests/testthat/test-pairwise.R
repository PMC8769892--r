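test_that("Tukey fences flag exactly the out-of-fence points", {
  expect_false(any(tukey_mask(1:10)))
  expect_identical(which(tukey_mask(c(1, 2, 3, 4, 5, 100))), 6L)
  expect_false(any(tukey_mask(c(5, 5, 5, 5))))  # IQR 0: fences at the value
  expect_warning(flags <- tukey_mask(c(1, 2, 3)), "fewer than 4")
  expect_false(any(flags))
})

test_that("Tukey fences agree with a sorting-based quantile oracle", {
  set.seed(301)
  for (rep in 1:100) {
    n <- sample(4:60, 1)
    v <- switch(sample(3, 1),
                rnorm(n), rexp(n), c(rnorm(n - 2), rnorm(2, 8)))
    expect_identical(tukey_mask(v), oracle_tukey(v))
  }
})

test_that("mixture fit selects one component for a single Gaussian blob", {
  set.seed(42)
  b <- rbvn(200, 0.3)
  fit <- fit_pair_clusters(b[, 1], b[, 2], seed = 5)
  expect_identical(fit$K, 1L)
  # brute-force selection: argmin of the per-k BIC the fit exposes
  expect_identical(fit$selected_k, which.min(fit$bic))
})

test_that("mixture fit separates two distant blobs and matches truth", {
  set.seed(43)
  truth <- rep(1:2, each = 100)
  x <- c(rnorm(100, 0, 0.5), rnorm(100, 10, 0.5))
  y <- c(rnorm(100, 0, 0.5), rnorm(100, 10, 0.5))
  fit <- fit_pair_clusters(x, y, seed = 5)
  expect_identical(fit$K, 2L)
  expect_identical(fit$selected_k, which.min(fit$bic))
  # perfect agreement up to label permutation
  expect_identical(length(unique(fit$labels[truth == 1])), 1L)
  expect_identical(length(unique(fit$labels[truth == 2])), 1L)
  expect_false(fit$labels[1] == fit$labels[200])
  # independent mixture implementation agrees on the component count
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  m <- Mclust(cbind(x, y), G = 1:5, modelNames = "VVV", verbose = FALSE)
  expect_identical(m$G, 2L)
})

test_that("too few samples yield zero clusters", {
  set.seed(44)
  fit <- fit_pair_clusters(rnorm(10), rnorm(10), min_cluster_size = 30)
  expect_identical(fit$K, 0L)
  expect_true(all(is.na(fit$labels)))
})

test_that("cluster outlier removal flags fence violations and drops small clusters", {
  # evenly spaced values sit strictly inside their own Tukey fences
  x <- seq(-1, 1, length.out = 40)
  y <- seq(2, 5, length.out = 40)
  labels <- rep(0L, 40)
  clean <- remove_cluster_outliers(x, y, labels, min_cluster_size = 10L)
  expect_identical(clean$labels, labels)
  expect_false(any(clean$outlier))
  # one extreme point is coded as removed
  x2 <- c(x, 20 * sd(x))
  y2 <- c(y, 0)
  res <- remove_cluster_outliers(x2, y2, rep(0L, 41), min_cluster_size = 10L)
  expect_true(res$outlier[41])
  expect_true(is.na(res$labels[41]))
  # removal shrinking a cluster below the floor drops the whole cluster
  res2 <- remove_cluster_outliers(x2, y2, rep(0L, 41), min_cluster_size = 41L)
  expect_true(all(is.na(res2$labels)))
})

test_that("per-cluster correlation matches closed forms", {
  x <- seq(-2, 2, length.out = 50)
  lab <- rep(0L, 50)
  expect_equal(cluster_correlation(x, 2 * x + 1, lab, "pearson")$r, 1)
  expect_equal(cluster_correlation(x, exp(x), lab, "spearman")$r, 1)
  expect_equal(cluster_correlation(x, -x, lab, "pearson")$r, -1)
  expect_equal(cluster_correlation(x, -x, lab, "spearman")$r, -1)
  # zero-variance cluster is excluded
  expect_identical(nrow(cluster_correlation(x, rep(1, 50), lab, "pearson")),
                   0L)
})

test_that("similarity pass finds the planted pair and only it", {
  set.seed(46)
  n <- 100
  a <- rnorm(n)
  gem <- rbind(A = a, B = a + rnorm(n, sd = 0.1), C = rnorm(n))
  colnames(gem) <- sprintf("S%03d", 1:n)
  out <- similarity_pass(gem, seed = 9)
  expect_identical(unique(out[, c("gene_i", "gene_j")]),
                   data.frame(gene_i = "A", gene_j = "B"))
  expect_gt(out$r[1], 0.98)
  # unattainable threshold: empty stream
  none <- similarity_pass(gem, min_abs_correlation = 1.01, seed = 9)
  expect_identical(nrow(none), 0L)
})

test_that("similarity pass is deterministic and conserves sample codes", {
  set.seed(47)
  n <- 120L
  gem <- matrix(rnorm(6 * n, mean = 5, sd = 0.7), nrow = 6,
                dimnames = list(paste0("g", 1:6), sprintf("S%03d", 1:n)))
  gem[1, ] <- gem[2, ] + rnorm(n, sd = 0.2)
  gem[cbind(sample(6, 30, replace = TRUE), sample(n, 30, replace = TRUE))] <- NA
  run1 <- similarity_pass(gem, seed = 13)
  run2 <- similarity_pass(gem, seed = 13)
  expect_identical(run1, run2)
  for (k in seq_len(nrow(run1))) {
    codes <- strsplit(run1$samples[k], "")[[1]]
    expect_identical(length(codes), n)
    expect_true(all(codes %in% c(as.character(0:5), "6", "7", "9")))
    # digit codes of this cluster match its recorded size
    expect_identical(sum(codes == as.character(run1$cluster_index[k])),
                     run1$cluster_size[k])
  }
})

test_that("recovered correlation of a bivariate normal is within 3 Fisher SEs", {
  set.seed(48)
  rho <- 0.7
  n <- 250
  b <- rbvn(n, rho)
  out <- similarity_pass(rbind(x = b[, 1], y = b[, 2],
                               z = rnorm(n)) |>
                           (\(m) {colnames(m) <- sprintf("S%03d", 1:n); m})(),
                         seed = 21)
  pair <- out[out$gene_i == "x" & out$gene_j == "y", ]
  expect_identical(nrow(pair), 1L)
  se <- 1 / sqrt(pair$cluster_size - 3)
  expect_lt(abs(atanh(pair$r) - atanh(rho)), 3 * se)
})

test_that("cluster file round trips", {
  sc <- small_scenario()
  f <- withr::local_tempfile()
  write_clusters(sc$clusters, f)
  back <- read_clusters(f)
  expect_equal(back$r, sc$clusters$r, tolerance = 1e-12)
  expect_identical(back$samples, sc$clusters$samples)
  expect_identical(back$cluster_size, sc$clusters$cluster_size)
})
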