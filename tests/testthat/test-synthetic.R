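test_that("the generator is fully deterministic under its seed", {
  a <- generateCausalNetwork(smallSimConfig(5))
  b <- generateCausalNetwork(smallSimConfig(5))
  expect_identical(networkEdges(a$network), networkEdges(b$network))
  expect_identical(a$truth$mechanismLabels, b$truth$mechanismLabels)
  c <- generateCausalNetwork(smallSimConfig(6))
  expect_false(identical(networkEdges(a$network), networkEdges(c$network)))
})

test_that("planted motif paths respect the mechanism step caps", {
  art <- generateCausalNetwork(smallSimConfig(2))
  lab <- art$truth$mechanismLabels
  steps <- lengths(strsplit(lab$path, ">", fixed = TRUE)) - 1L
  expect_true(all(steps[lab$mechanism == "M1"] <= 2))
  expect_true(all(steps[lab$mechanism == "M2"] <= 2))  # no more than two
  expect_true(all(steps[lab$mechanism == "M3"] <= 3))
  expect_true(all(steps >= 1))
})

test_that("every planted path exists in the emitted network", {
  art <- generateCausalNetwork(smallSimConfig(3))
  lab <- art$truth$mechanismLabels
  expect_true(all(vapply(lab$path, pathExistsInNetwork,
                         net = art$network, TRUE)))
  # and every path starts at an inhibited kinase of its treatment
  starts <- vapply(strsplit(lab$path, ">", fixed = TRUE), `[`, "", 1)
  expected <- unlist(art$inhibitorMap[lab$treatment])
  expect_identical(unname(starts), unname(expected))
})

test_that("generator sign bookkeeping matches sign propagation", {
  art <- generateCausalNetwork(smallSimConfig(4))
  net <- art$network
  mo <- art$motifs
  propagate <- function(pathStr) {
    nodes <- strsplit(pathStr, ">", fixed = TRUE)[[1]]
    propagatePerturbationSign(pepwire:::.pathEdges(net, nodes))
  }
  expect_identical(vapply(mo$m1$path, propagate, 1L, USE.NAMES = FALSE),
                   mo$m1$ukActivity)
  expect_identical(vapply(mo$m2$path, propagate, 1L, USE.NAMES = FALSE),
                   mo$m2$ukActivity)
  expect_identical(vapply(mo$m3$path, propagate, 1L, USE.NAMES = FALSE),
                   mo$m3$phSign)
})

test_that("stability motifs couple site, protein and peptide signs", {
  art <- generateCausalNetwork(smallSimConfig(7))
  m2 <- art$motifs$m2
  siteSign <- m2$ukActivity  # phospho follows kinase activity
  expect_identical(m2$proteinSign,
                   siteSign * ifelse(m2$stabilizes, 1L, -1L))
  expect_identical(m2$pepSign, -m2$proteinSign)
  # destabilizing site with phospho down: stability up, peptide down
  down_destab <- !m2$stabilizes & siteSign == -1L
  expect_true(all(m2$proteinSign[down_destab] == 1L))
  expect_true(all(m2$pepSign[down_destab] == -1L))
})

test_that("zero noise collapses replicates onto condition means", {
  cfg <- smallSimConfig(9, replicateNoiseSd = 0)
  sim <- simulateOmicsLayers(generateCausalNetwork(cfg), cfg)
  for (x in sim$layers) {
    m <- intensities(x)
    d <- sampleDesign(x)
    for (cond in d@conditions) {
      sub <- m[, d@condition == cond, drop = FALSE]
      expect_equal(apply(sub, 1, max), apply(sub, 1, min))
    }
    # unplanted features are flat across all conditions at their baseline
    planted <- unique(sim$truth$plantedEffects$feature_id[
      sim$truth$plantedEffects$layer == layerType(x)])
    flat <- setdiff(rownames(m), planted)
    expect_equal(apply(m[flat, , drop = FALSE], 1, max),
                 apply(m[flat, , drop = FALSE], 1, min))
  }
})

test_that("planted fold-changes are recovered on average across seeds", {
  cfg0 <- smallSimConfig(1)
  art <- generateCausalNetwork(cfg0)
  pep <- art$motifs$m2$pepId[1]
  trt <- art$motifs$m2$treatment[1]
  planted <- cfg0$plantedEffectLog2 * art$motifs$m2$pepSign[1]
  lfc <- vapply(1:50, function(s) {
    cfg <- smallSimConfig(1)      # same network seed, new noise seed
    cfg$rngSeed <- 1000L + s
    sim <- simulateOmicsLayers(art, cfg)
    m <- intensities(sim$layers$immunopeptidome)
    d <- sampleDesign(sim$layers$immunopeptidome)
    mean(m[pep, d@condition == trt]) -
      mean(m[pep, d@condition == d@control])
  }, 1.0)
  sem <- cfg0$replicateNoiseSd * sqrt(2 / cfg0$replicates) / sqrt(50)
  expect_lt(abs(mean(lfc) - planted), 3 * sem)
})

test_that("the censoring model is intensity-dependent and seeded", {
  d <- toyDesign()
  cfg <- smallSimConfig(1, missingPMax = 0.3, missingSlope = 1,
                        missingMidpoint = 20)
  low <- matrix(10, nrow = 850, ncol = 12)   # far below the midpoint
  high <- matrix(30, nrow = 850, ncol = 12)  # far above
  rownames(low) <- sprintf("lo%03d", 1:850)
  rownames(high) <- sprintf("hi%03d", 1:850)
  colnames(low) <- colnames(high) <- d@sampleIds
  xl <- applyMissingness(OmicsLayer(low, "proteome", d), cfg, seed = 4)
  xh <- applyMissingness(OmicsLayer(high, "proteome", d), cfg, seed = 4)
  rateLow <- mean(is.na(intensities(xl)))    # 10,200 cells
  rateHigh <- mean(is.na(intensities(xh)))
  # saturated stratum hits missingPMax within a 3-sigma binomial band
  n <- length(low)
  expect_lt(abs(rateLow - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_gt(rateLow, rateHigh)               # monotone in intensity
  expect_lt(rateHigh, 0.01)
  # seeded and sensitive to the seed
  again <- applyMissingness(OmicsLayer(low, "proteome", d), cfg, seed = 4)
  expect_identical(intensities(again), intensities(xl))
  other <- applyMissingness(OmicsLayer(low, "proteome", d), cfg, seed = 5)
  expect_false(identical(intensities(other), intensities(xl)))
  # missingPMax = 0 leaves the matrix untouched
  cfg0 <- smallSimConfig(1, missingPMax = 0)
  expect_identical(intensities(applyMissingness(
    OmicsLayer(low, "proteome", d), cfg0)), low)
})

test_that("cohort structure plants TAAs outside the benign compartment", {
  cfg <- smallSimConfig(12)
  study <- simulateStudy(cfg)
  taa <- study$truth$plantedTAAs
  coh <- study$cohort$cohortPresence
  ben <- study$cohort$benignPresence
  expect_true(all(coh[taa] >= 1))
  expect_true(all(ben[taa] == 0 | is.na(ben[taa])))
  binders <- binderPeptides(study$cohort$binderTable)
  expect_true(all(taa %in% binders))  # strong or weak by construction
  # end-to-end set oracle: the TAA caller returns exactly the planted set
  expect_identical(identifyTAAs(binders, coh, ben), sort(taa))
})
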