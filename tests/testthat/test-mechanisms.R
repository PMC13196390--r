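test_that("perturbation signs multiply along contiguous paths", {
  p2 <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   sign = c(1L, 1L))
  expect_identical(propagatePerturbationSign(p2), -1L)  # inhibition passes
  p2$sign <- c(1L, -1L)
  expect_identical(propagatePerturbationSign(p2), 1L)
  expect_identical(propagatePerturbationSign(p2[0, ]), -1L)  # empty path
  expect_identical(propagatePerturbationSign(p2, initialSign = 1L), -1L)
  bad <- data.frame(source = c("A", "X"), target = c("B", "C"),
                    sign = 1L)
  expect_error(propagatePerturbationSign(bad), "non-contiguous")
})

test_that("stability sign algebra matches the truth table", {
  # kinase activity = -pathSign; site phospho follows the kinase; protein
  # follows site x effect; peptide opposes the protein
  for (pathSign in c(1L, -1L)) for (stabilizes in c(TRUE, FALSE)) {
    ukAct <- -1L * pathSign
    predicted <- -(ukAct * (if (stabilizes) 1L else -1L))
    for (mode in c("lenient", "strict")) {
      fx <- signFixture(pathSign, stabilizes, observedPep = predicted)
      out <- assignMechanism2(fx$pepRes, fx$ann, fx$sites, fx$net, fx$map,
                              cfg = analysisConfig(consistencyMode = mode))
      expect_identical(nrow(out), 1L)
      expect_identical(out$predicted_sign, predicted)
      expect_true(out$consistent)       # matching peptide, no supports
      # flipped observation is never consistent
      flip <- signFixture(pathSign, stabilizes, observedPep = -predicted)
      out2 <- assignMechanism2(flip$pepRes, flip$ann, flip$sites, flip$net,
                               flip$map,
                               cfg = analysisConfig(consistencyMode = mode))
      expect_false(out2$consistent)
    }
  }
})

test_that("destabilizing site with phospho down predicts peptide down", {
  # site phospho down -> stability up -> protein up -> peptide down
  fx <- signFixture(pathSign = 1L, stabilizes = FALSE, observedPep = -1L,
                    siteObs = -1L, protObs = 1L)
  out <- assignMechanism2(fx$pepRes, fx$ann, fx$sites, fx$net, fx$map,
                          fx$phosphoRes, fx$protRes,
                          cfg = analysisConfig(consistencyMode = "strict"))
  expect_identical(out$predicted_sign, -1L)
  expect_true(out$consistent)
  expect_identical(out$support_site_sign, -1L)
  expect_identical(out$support_protein_sign, 1L)
})

test_that("supporting layers gate the verdict by mode", {
  # site phospho observed opposite to its prediction
  fx <- signFixture(pathSign = 1L, stabilizes = FALSE, observedPep = -1L,
                    siteObs = 1L)
  lenientOut <- assignMechanism2(fx$pepRes, fx$ann, fx$sites, fx$net,
                                 fx$map, fx$phosphoRes,
                                 cfg = analysisConfig())
  expect_false(lenientOut$consistent)  # significant mismatch counts
  # a measured-but-unchanged support: ignored lenient, fatal strict
  fx0 <- signFixture(pathSign = 1L, stabilizes = FALSE, observedPep = -1L,
                     siteObs = 0L)
  expect_true(assignMechanism2(fx0$pepRes, fx0$ann, fx0$sites, fx0$net,
                               fx0$map, fx0$phosphoRes,
                               cfg = analysisConfig())$consistent)
  expect_false(assignMechanism2(fx0$pepRes, fx0$ann, fx0$sites, fx0$net,
                                fx0$map, fx0$phosphoRes,
                                cfg = analysisConfig(
                                  consistencyMode = "strict"))$consistent)
})

test_that("paths over the step cap emit no stability assignment", {
  # IK -> A -> B -> UK is three steps, one over the default cap
  net <- CausalNetwork(
    nodes = data.frame(id = c("IK", "A", "B", "UK", "P"),
                       is_kinase = c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    edges = data.frame(source = c("IK", "A", "B", "UK"),
                       target = c("A", "B", "UK", "P"), sign = 1L,
                       edge_type = c("other", "other", "other",
                                     "phosphorylation"),
                       site_residue = c(NA, NA, NA, "S"),
                       site_position = c(NA, NA, NA, 39L)))
  fx <- signFixture(1L, TRUE, observedPep = 1L)
  out <- assignMechanism2(fx$pepRes, fx$ann, fx$sites, net, fx$map,
                          cfg = analysisConfig())
  expect_identical(nrow(out), 0L)
  # raising the cap restores it (monotonicity in the cap)
  out3 <- assignMechanism2(fx$pepRes, fx$ann, fx$sites, net, fx$map,
                           cfg = analysisConfig(m2MaxSteps = 3))
  expect_identical(nrow(out3), 1L)
  expect_identical(out3$n_steps, 3L)
})

test_that("zero-noise synthetic runs recover every planted mechanism", {
  cfg <- smallSimConfig(31, replicateNoiseSd = 0, missingPMax = 0)
  study <- simulateStudy(cfg, missingness = FALSE)
  acfg <- analysisConfig()
  res <- suppressWarnings(
    lapply(study$layers, differentialTest, cfg = acfg))
  a1 <- assignMechanism1(res$phospho_immunopeptidome, study$annotations,
                         study$siteAnnotations, study$network,
                         study$inhibitorMap, res$phosphoproteome, acfg)
  a2 <- assignMechanism2(res$immunopeptidome, study$annotations,
                         study$siteAnnotations, study$network,
                         study$inhibitorMap, res$phosphoproteome,
                         res$proteome, acfg)
  a3 <- assignMechanism3(res$immunopeptidome, res$proteome,
                         res$phosphoproteome, study$tfTargets,
                         study$annotations, study$siteAnnotations,
                         study$network, study$inhibitorMap, acfg)
  all3 <- rbind(a1, a2, a3)
  rec <- evaluateRecovery(all3, study$truth)
  expect_equal(rec$perMechanism$precision, c(1, 1, 1))
  expect_equal(rec$perMechanism$recall, c(1, 1, 1))
  # no consistent assignment lands on a background peptide
  planted <- unique(study$truth$mechanismLabels$peptide_id)
  expect_true(all(all3$peptide_id[all3$consistent] %in% planted))
  # every emitted path is independently verified in the network
  expect_true(all(vapply(unique(all3$path), pathExistsInNetwork,
                         net = study$network, TRUE)))
  # strict mode is also exact here: every support was planted consistently
  a2s <- assignMechanism2(res$immunopeptidome, study$annotations,
                          study$siteAnnotations, study$network,
                          study$inhibitorMap, res$phosphoproteome,
                          res$proteome,
                          analysisConfig(consistencyMode = "strict"))
  recS <- evaluateRecovery(rbind(a1, a2s, a3), study$truth)
  expect_equal(recS$perMechanism$recall[2], 1)
})

test_that("negative TF regulation flips the predicted direction", {
  net <- CausalNetwork(
    nodes = data.frame(id = c("IK", "TF", "G1", "G2"),
                       is_kinase = c(TRUE, FALSE, FALSE, FALSE),
                       is_tf = c(FALSE, TRUE, FALSE, FALSE)),
    edges = data.frame(source = c("IK", "TF", "TF"),
                       target = c("TF", "G1", "G2"),
                       sign = c(1L, 1L, -1L),
                       edge_type = c("phosphorylation", "transcriptional",
                                     "transcriptional"),
                       site_residue = c("S", NA, NA),
                       site_position = c(727L, NA, NA)))
  tft <- data.frame(tf_id = "TF", target_id = c("G1", "G2"),
                    regulation_sign = c(1L, -1L))
  sites <- data.frame(protein_id = "TF", residue = "S", position = 727L,
                      functional_effect = "activates_protein",
                      upstream_kinases = "IK", stringsAsFactors = FALSE)
  ann <- data.frame(feature_id = c("p1", "p2"),
                    feature_kind = "hla_peptide",
                    peptide_sequence = c("AAAAAAAAA", "CCCCCCCCC"),
                    source_protein = c("G1", "G2"), site_protein = NA,
                    site_residue = NA, site_position = NA,
                    stringsAsFactors = FALSE)
  pepRes <- data.frame(feature_id = c("p1", "p2"),
                       layer = "immunopeptidome", treatment = "drug",
                       log2FC = c(-2, 2), t_statistic = c(-9, 9),
                       p_value = 1e-6, adj_p_value = 1e-6,
                       significant = TRUE, direction = c("down", "up"),
                       stringsAsFactors = FALSE)
  out <- assignMechanism3(pepRes, NULL, NULL, tft, ann, sites, net,
                          list(drug = "IK"), analysisConfig())
  # inhibition -> TF activity down; +1 edge: target down; -1 edge: up
  expect_identical(out$predicted_sign[out$peptide_id == "p1"], -1L)
  expect_identical(out$predicted_sign[out$peptide_id == "p2"], 1L)
  expect_true(all(out$consistent))
  # a TF with no annotated activity site is flagged but still propagated
  out2 <- assignMechanism3(pepRes, NULL, NULL, tft, ann, sites[0, ], net,
                           list(drug = "IK"), analysisConfig())
  expect_true(all(out2$flags == "no_activity_site"))
  expect_identical(out2$predicted_sign, out$predicted_sign)
})

test_that("recovery scoring does confusion-matrix arithmetic", {
  truth <- list(mechanismLabels = data.frame(
    peptide_id = sprintf("p%02d", 1:10), treatment = "drug",
    mechanism = "M1", path = "IK>UK", expected_sign = -1L,
    stringsAsFactors = FALSE))
  mkAssign <- function(peps) if (!length(peps))
    mkAssign("placeholder")[0, ] else data.frame(
    peptide_id = peps, treatment = "drug", mechanism = "M1",
    path = "IK>UK", n_steps = 1L, entity = "UK", site = "",
    predicted_sign = -1L, observed_sign = -1L,
    support_kinase_sign = NA_integer_, support_site_sign = NA_integer_,
    support_protein_sign = NA_integer_, consistent = TRUE,
    mode = "lenient", flags = "", stringsAsFactors = FALSE)
  perfect <- evaluateRecovery(mkAssign(sprintf("p%02d", 1:10)), truth)
  expect_equal(perfect$overall$precision, 1)
  expect_equal(perfect$overall$recall, 1)
  nine <- evaluateRecovery(mkAssign(c(sprintf("p%02d", 1:9), "spurious")),
                           truth)
  expect_equal(nine$overall$precision, 0.9)
  expect_equal(nine$overall$recall, 0.9)
  empty <- evaluateRecovery(mkAssign(character(0)), truth)
  expect_equal(empty$overall$recall, 0)
  expect_equal(empty$overall$precision, 1)  # convention, flagged
  expect_identical(empty$flag, "no_predictions")
})

test_that("raising a step cap never removes an assignment", {
  cfg <- smallSimConfig(33, replicateNoiseSd = 0, missingPMax = 0)
  study <- simulateStudy(cfg, missingness = FALSE)
  res <- suppressWarnings(
    lapply(study$layers, differentialTest, cfg = analysisConfig()))
  key <- function(a) paste(a$peptide_id, a$treatment, a$path)
  for (cap in 1:3) {
    lo <- assignMechanism3(res$immunopeptidome, res$proteome,
                           res$phosphoproteome, study$tfTargets,
                           study$annotations, study$siteAnnotations,
                           study$network, study$inhibitorMap,
                           analysisConfig(m3MaxSteps = cap))
    hi <- assignMechanism3(res$immunopeptidome, res$proteome,
                           res$phosphoproteome, study$tfTargets,
                           study$annotations, study$siteAnnotations,
                           study$network, study$inhibitorMap,
                           analysisConfig(m3MaxSteps = cap + 1L))
    expect_true(all(key(lo) %in% key(hi)))
  }
})
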