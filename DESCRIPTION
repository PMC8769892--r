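Package: csgcn
Title: Context-Specific Gene Co-Expression Network Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds context-specific gene co-expression networks (csGCNs) from
    a log-scale gene expression matrix and per-sample annotations. For every
    gene pair the workflow removes outliers (Tukey fences), clusters the
    pairwise scatter with bivariate Gaussian mixture models, removes
    per-cluster outliers, scores each cluster by Pearson or Spearman
    correlation, discards clusters whose sample size cannot statistically
    support their correlation (Fisher-z power analysis), associates surviving
    clusters with experimental conditions (proportion z-tests for categories,
    per-gene linear regression for quantitative covariates), and filters
    associations biased by shared missingness patterns (Student's t-test) or
    by confounding covariates (Welch's ANOVA on each gene). Retained clusters
    become ranked, condition-annotated network edges. Also provides an
    edge-assumption audit (Royston multivariate normality, Breusch-Pagan
    heteroscedasticity, mixture-model multimodality) and a synthetic-data
    generator that plants condition-specific co-expression structure with
    ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    lmtest,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
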