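test_that("detection filter keeps 2-of-3-in-one-condition features", {
  d <- toyDesign()
  m <- matrix(NA_real_, nrow = 3, ncol = 12,
              dimnames = list(c("ctrl_only", "sparse", "full"),
                              d@sampleIds))
  m["ctrl_only", d@condition == "control"] <- 20      # 3/3 in control only
  m["sparse", c(1, 4, 7, 10)] <- 20                   # 1/3 everywhere
  m["full", ] <- 20
  x <- OmicsLayer(m, "immunopeptidome", d, scale = "log2")
  kept <- rownames(log2AndFilter(x))
  expect_true("ctrl_only" %in% kept)   # detected in at least one condition
  expect_false("sparse" %in% kept)
  expect_true("full" %in% kept)
})

test_that("retained set equals the brute-force detection predicate", {
  d <- toyDesign()
  set.seed(11)
  m <- matrix(rnorm(200 * 12, 25, 2), nrow = 200,
              dimnames = list(sprintf("f%03d", 1:200), d@sampleIds))
  m[runif(length(m)) < 0.45] <- NA
  x <- OmicsLayer(m, "proteome", d, scale = "log2")
  kept <- rownames(log2AndFilter(x))
  oracle <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
    any(vapply(d@conditions, function(cond)
      sum(!is.na(m[i, d@condition == cond])) >= 2, TRUE))
  }, TRUE)]
  expect_identical(kept, oracle)
})

test_that("raw matrices are log2-transformed and non-positive values fail", {
  d <- toyDesign(c("control", "drug"))
  m <- matrix(2^seq(1, 24, length.out = 24), nrow = 4,
              dimnames = list(paste0("f", 1:4), d@sampleIds))
  x <- log2AndFilter(OmicsLayer(m, "proteome", d, scale = "raw"))
  expect_equal(intensities(x), log2(m))
  m[2, 3] <- -1
  expect_error(log2AndFilter(OmicsLayer(m, "proteome", d, scale = "raw")),
               "f2")
})

test_that("MinProb imputation fills from the low-intensity tail only", {
  d <- toyDesign()
  set.seed(5)
  m <- matrix(rnorm(500 * 12, 25, 2), nrow = 500,
              dimnames = list(sprintf("f%03d", 1:500), d@sampleIds))
  holes <- sample(length(m), 400)
  m[holes] <- NA
  x <- OmicsLayer(m, "immunopeptidome", d, scale = "log2")
  cfg <- analysisConfig()

  y <- imputeMinProb(x, cfg, seed = 9)
  v <- intensities(y)
  expect_false(anyNA(v))
  # observed cells bitwise unchanged
  expect_identical(v[!is.na(m)], m[!is.na(m)])
  # imputed values lie within mu +/- 6 sigma of their sample's model
  for (j in seq_len(ncol(m))) {
    obs <- m[!is.na(m[, j]), j]
    mu <- quantile(obs, cfg$imputationQ, names = FALSE)
    sig <- cfg$imputationSdScale * sd(obs)
    imp <- v[is.na(m[, j]), j]
    expect_true(all(abs(imp - mu) < 6 * sig))
  }
  # determinism: same seed identical, new seed changes imputed cells only
  expect_identical(intensities(imputeMinProb(x, cfg, seed = 9)), v)
  v2 <- intensities(imputeMinProb(x, cfg, seed = 10))
  expect_identical(v2[!is.na(m)], m[!is.na(m)])
  expect_false(identical(v2[is.na(m)], v[is.na(m)]))

  # no missing cells: returned unchanged
  full <- OmicsLayer(v, "immunopeptidome", d, scale = "log2")
  expect_identical(intensities(imputeMinProb(full, cfg)), v)
})

test_that("imputed values are centered on the q = 0.01 sample quantile", {
  d <- toyDesign(c("control", "drug"), replicates = 2L)
  set.seed(2)
  m <- matrix(rnorm(2000 * 4, 25, 2), nrow = 2000,
              dimnames = list(sprintf("f%04d", 1:2000), d@sampleIds))
  m[1:1000, 1] <- NA  # >= 1000 draws in sample 1
  x <- OmicsLayer(m, "proteome", d, scale = "log2")
  cfg <- analysisConfig()
  obs <- m[!is.na(m[, 1]), 1]
  mu <- quantile(obs, cfg$imputationQ, names = FALSE)
  sig <- cfg$imputationSdScale * sd(obs)
  imp <- intensities(imputeMinProb(x, cfg, seed = 1))[1:1000, 1]
  expect_lt(abs(mean(imp) - mu), 3 * sig / sqrt(1000))
})

test_that("a sample with fewer than two observations is an error", {
  d <- toyDesign(c("control", "drug"), replicates = 2L)
  m <- matrix(rnorm(12, 20), nrow = 3,
              dimnames = list(paste0("f", 1:3), d@sampleIds))
  m[1:2, 2] <- NA
  x <- OmicsLayer(m, "proteome", d, scale = "log2")
  expect_error(imputeMinProb(x, analysisConfig(), seed = 1),
               "fewer than 2 observed")
})

test_that("the worked differential example matches the closed form", {
  # control (10.0, 10.2, 9.8) vs treatment (12.0, 12.2, 11.8):
  # pooled sd 0.2, df 4 => t = 2 / (0.2 * sqrt(2/3)) = 12.2474487,
  # p = 2 * pt(-t, 4) = 2.5521675e-4 (frozen from the closed form)
  d <- toyDesign(c("control", "drug"))
  m <- matrix(c(10.0, 10.2, 9.8, 12.0, 12.2, 11.8), nrow = 1,
              dimnames = list("f1", d@sampleIds))
  res <- differentialTest(OmicsLayer(m, "proteome", d, scale = "log2"))
  expect_equal(res$log2FC, 2.0)
  expect_equal(res$t_statistic, 12.2474487139159, tolerance = 1e-10)
  expect_equal(res$p_value, 2.55216749442558e-04, tolerance = 1e-10)
  expect_true(res$significant)
  expect_identical(res$direction, "up")
})

test_that("vectorized t-tests agree with stats::t.test feature by feature", {
  d <- toyDesign()
  set.seed(3)
  m <- matrix(rnorm(40 * 12, 22, 1), nrow = 40,
              dimnames = list(sprintf("f%02d", 1:40), d@sampleIds))
  x <- OmicsLayer(m, "proteome", d, scale = "log2")
  for (ve in c(TRUE, FALSE)) {
    res <- differentialTest(x, analysisConfig(varEqual = ve))
    orc <- tTestOracle(m, d, varEqual = ve)
    key <- paste(res$feature_id, res$treatment)
    okey <- paste(orc$feature_id, orc$treatment)
    expect_equal(res$log2FC, orc$log2FC[match(key, okey)])
    expect_equal(res$t_statistic, orc$t_statistic[match(key, okey)],
                 tolerance = 1e-12)
    expect_equal(res$p_value, orc$p_value[match(key, okey)],
                 tolerance = 1e-12)
    # BH adjustment within each treatment family
    for (trt in treatments(d)) {
      sub <- res[res$treatment == trt, ]
      expect_equal(sub$adj_p_value, p.adjust(sub$p_value, "BH"))
    }
  }
})

test_that("significance needs both the fold-change and the FDR gate", {
  d <- toyDesign(c("control", "drug"), replicates = 3L)
  # tiny variance makes adj_p ~ 1e-5 but |log2FC| = 0.4 < 0.5
  m <- matrix(c(10, 10.001, 9.999, 10.4, 10.401, 10.399), nrow = 1,
              dimnames = list("f1", d@sampleIds))
  res <- differentialTest(OmicsLayer(m, "proteome", d, scale = "log2"))
  expect_lt(res$adj_p_value, 0.001)
  expect_false(res$significant)
  expect_identical(res$direction, "none")
})

test_that("identical groups give log2FC 0 and direction none", {
  d <- toyDesign(c("control", "drug"))
  m <- matrix(rep(c(9, 10, 11), 2), nrow = 1,
              dimnames = list("f1", d@sampleIds))
  res <- differentialTest(OmicsLayer(m, "proteome", d, scale = "log2"))
  expect_equal(res$log2FC, 0)
  expect_identical(res$direction, "none")
})

test_that("zero pooled variance degenerates to p = 0 or 1 with a warning", {
  d <- toyDesign(c("control", "drug"))
  m <- matrix(c(rep(10, 3), rep(12, 3), rep(8, 6)), nrow = 2,
              byrow = TRUE, dimnames = list(c("moved", "flat"),
                                            d@sampleIds))
  expect_warning(
    res <- differentialTest(OmicsLayer(m, "proteome", d, scale = "log2")),
    "zero pooled variance")
  expect_equal(res$p_value[res$feature_id == "moved"], 0)
  expect_equal(res$p_value[res$feature_id == "flat"], 1)
  expect_true(res$significant[res$feature_id == "moved"])
})

test_that("count summaries partition significant features by direction", {
  d <- toyDesign()
  set.seed(8)
  m <- matrix(rnorm(300 * 12, 25, 0.5), nrow = 300,
              dimnames = list(sprintf("f%03d", 1:300), d@sampleIds))
  m[1:60, d@condition == "PP2"] <- m[1:60, d@condition == "PP2"] +
    rep(c(3, -3), 30)
  res <- differentialTest(OmicsLayer(m, "immunopeptidome", d,
                                     scale = "log2"))
  cnt <- summarizeCounts(res)
  expect_true(all(cnt$up + cnt$down == cnt$total))
  for (i in seq_len(nrow(cnt))) {   # brute-force tally
    sub <- res[res$treatment == cnt$treatment[i] & res$significant, ]
    expect_identical(cnt$up[i], sum(sub$log2FC > 0))
    expect_identical(cnt$down[i], sum(sub$log2FC < 0))
  }
  # zero significant -> all zero counts
  none <- res; none$significant <- FALSE; none$direction <- "none"
  expect_true(all(summarizeCounts(none)$total == 0))
})

test_that("stronger planted effects never recover fewer features", {
  d <- toyDesign(c("control", "drug"))
  recovered <- vapply(c(1, 2, 4), function(eff) {
    set.seed(21)
    m <- matrix(rnorm(400 * 6, 25, 0.5), nrow = 400,
                dimnames = list(sprintf("f%03d", 1:400), d@sampleIds))
    m[1:100, d@condition == "drug"] <- m[1:100, d@condition == "drug"] + eff
    res <- differentialTest(OmicsLayer(m, "immunopeptidome", d,
                                       scale = "log2"))
    sum(res$significant[match(sprintf("f%03d", 1:100), res$feature_id)])
  }, 1L)
  expect_true(all(diff(recovered) >= 0))
})
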