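#' @importFrom stats rnorm runif rbinom quantile plogis sd
NULL

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.randomPeptides <- function(n, len = 9L) {
  seqs <- character(0)
  while (length(seqs) < n) {
    more <- vapply(seq_len(n - length(seqs)), function(i)
      paste(sample(.AA, len, replace = TRUE), collapse = ""), "")
    seqs <- unique(c(seqs, more))
  }
  seqs[seq_len(n)]
}

.pathString <- function(nodes) paste(nodes, collapse = ">")

#' Generate a signed causal network with planted mechanism motifs
#'
#' Builds, per inhibitor treatment, three families of regulatory motifs:
#' direct phosphorylation of a presented peptide (M1: inhibited kinase ->
#' upstream kinase -> phosphosite on a presented peptide), source-protein
#' stability control (M2: the targeted site stabilizes or destabilizes its
#' protein), and transcription-factor control (M3: a TF with an
#' activity-reporting phosphosite and signed target genes). Around the
#' motifs it places background signaling nodes with random signed edges,
#' decoy drug-reachable TFs without planted effects, and an antigen
#' processing and presentation pathway node set wired so that the inhibited
#' kinases are proximal to it. All motif wiring is recorded in a partial
#' ground-truth ledger.
#'
#' @param cfg a [simulationConfig()].
#' @return a list with elements `network` ([CausalNetwork-class]),
#'   `siteAnnotations`, `tfTargets` (data.frames), `inhibitorMap` (named
#'   list), `design` ([SampleDesign-class]), `truth` (partial ground truth
#'   with `mechanismLabels` and `candidateKinases`) and `motifs` (the
#'   internal motif registry consumed by [simulateOmicsLayers()]).
#' @export
generateCausalNetwork <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(deriveSeed(cfg$rngSeed, 1L), .generateCausalNetwork(cfg))
}

.generateCausalNetwork <- function(cfg) {
  design <- SampleDesign(cfg$conditions, cfg$control, cfg$replicates)
  trts <- treatments(design)
  ikPool <- c("BCR-ABL", "LCK", "JNK")
  ik <- if (length(trts) <= 3L &&
            identical(trts, c("imatinib", "PP2", "SP600125")[seq_along(trts)]))
    ikPool[seq_along(trts)] else paste0("IK_", trts)
  inhibitorMap <- stats::setNames(as.list(ik), trts)

  nodes <- data.frame(id = character(), is_kinase = logical(),
                      is_tf = logical(), is_druggable = logical(),
                      family_members = character(),
                      in_target_pathway = logical(),
                      stringsAsFactors = FALSE)
  addNode <- function(id, kin = FALSE, tf = FALSE, drug = FALSE,
                      fam = "", path = FALSE) {
    data.frame(id = id, is_kinase = kin, is_tf = tf, is_druggable = drug,
               family_members = fam, in_target_pathway = path,
               stringsAsFactors = FALSE)
  }
  edges <- list()
  addEdge <- function(src, tgt, sign, type = "other",
                      res = NA_character_, pos = NA_integer_) {
    data.frame(source = src, target = tgt, sign = as.integer(sign),
               edge_type = type, site_residue = res, site_position = pos,
               stringsAsFactors = FALSE)
  }

  nodes <- rbind(nodes,
                 do.call(rbind, lapply(ik, function(k)
                   addNode(k, kin = TRUE, drug = TRUE))))
  if ("LCK" %in% ik) {
    nodes <- rbind(nodes, addNode("FYN", kin = TRUE, drug = TRUE),
                   addNode("SFK", kin = TRUE, drug = TRUE,
                           fam = "LCK,FYN"))
  }
  appm <- c("TAP1", "TAP2", "ERAP1", "TAPBP", "B2M")
  nodes <- rbind(nodes, do.call(rbind, lapply(appm, function(a)
    addNode(a, path = TRUE))))

  # wire each inhibited kinase close to the target pathway: one direct edge
  # plus three two-step connector paths
  for (t in seq_along(ik)) {
    k <- ik[t]
    edges <- c(edges, list(addEdge(k, appm[1 + (t %% length(appm))],
                                   sample(c(-1L, 1L), 1))))
    for (j in 1:3) {
      cn <- sprintf("CONN_%s_%d", k, j)
      nodes <- rbind(nodes, addNode(cn))
      edges <- c(edges,
                 list(addEdge(k, cn, sample(c(-1L, 1L), 1)),
                      addEdge(cn, appm[1 + ((t + j) %% length(appm))],
                              sample(c(-1L, 1L), 1))))
    }
  }

  sites <- list()
  addSite <- function(protein, res, pos, effect, upstream) {
    data.frame(protein_id = protein, residue = res, position = as.integer(pos),
               functional_effect = effect,
               upstream_kinases = paste(upstream, collapse = ","),
               stringsAsFactors = FALSE)
  }
  tfTargets <- list()
  m1 <- list(); m2 <- list(); m3 <- list()
  labels <- list()

  nm <- cfg$nMotifsPerMechanism
  for (t in seq_along(trts)) {
    trt <- trts[t]; k0 <- ik[t]
    for (i in seq_len(nm)) {
      ## --- Mechanism 1: direct phosphorylation of a presented peptide ---
      steps <- 1L + (i %% 2L)
      uk <- sprintf("UK1_%s_%d", trt, i)
      pathNodes <- k0; ukAct <- -1L
      if (steps == 2L) {
        im <- sprintf("KM1_%s_%d", trt, i)
        e1 <- sample(c(-1L, 1L), 1)
        nodes <- rbind(nodes, addNode(im, kin = TRUE))
        edges <- c(edges, list(addEdge(k0, im, e1)))
        pathNodes <- c(pathNodes, im); ukAct <- ukAct * e1
      }
      e2 <- sample(c(-1L, 1L), 1)
      nodes <- rbind(nodes, addNode(uk, kin = TRUE))
      edges <- c(edges, list(addEdge(pathNodes[length(pathNodes)], uk, e2)))
      pathNodes <- c(pathNodes, uk); ukAct <- ukAct * e2
      sites <- c(sites, list(addSite(uk, "T", 161L, "activates_protein",
                                     pathNodes[length(pathNodes) - 1L])))
      sp <- sprintf("SP1_%s_%d", trt, i)
      pos <- 300L + i
      nodes <- rbind(nodes, addNode(sp))
      edges <- c(edges, list(addEdge(uk, sp, 1L, "phosphorylation",
                                     "T", pos)))
      sites <- c(sites, list(addSite(sp, "T", pos, "activates_protein", uk)))
      pepId <- sprintf("PHP_M1_%s_%d", trt, i)
      m1 <- c(m1, list(data.frame(
        treatment = trt, uk = uk, path = .pathString(pathNodes),
        ukActivity = ukAct, ukSiteFeature = paste0(uk, "_T161"),
        srcProtein = sp, siteRes = "T", sitePos = pos,
        pepId = pepId, pepSign = ukAct, stringsAsFactors = FALSE)))
      labels <- c(labels, list(data.frame(
        peptide_id = pepId, treatment = trt, mechanism = "M1",
        path = .pathString(pathNodes), expected_sign = ukAct,
        stringsAsFactors = FALSE)))

      ## --- Mechanism 2: source-protein stability control ---
      steps <- 1L + ((i + 1L) %% 2L)
      uk <- sprintf("UK2_%s_%d", trt, i)
      pathNodes <- k0; ukAct <- -1L
      if (steps == 2L) {
        im <- sprintf("KM2_%s_%d", trt, i)
        e1 <- sample(c(-1L, 1L), 1)
        nodes <- rbind(nodes, addNode(im, kin = TRUE))
        edges <- c(edges, list(addEdge(k0, im, e1)))
        pathNodes <- c(pathNodes, im); ukAct <- ukAct * e1
      }
      e2 <- sample(c(-1L, 1L), 1)
      nodes <- rbind(nodes, addNode(uk, kin = TRUE))
      edges <- c(edges, list(addEdge(pathNodes[length(pathNodes)], uk, e2)))
      pathNodes <- c(pathNodes, uk); ukAct <- ukAct * e2
      sites <- c(sites, list(addSite(uk, "T", 161L, "activates_protein",
                                     pathNodes[length(pathNodes) - 1L])))
      sp <- sprintf("SP2_%s_%d", trt, i)
      stabilizes <- runif(1) < 0.5
      nodes <- rbind(nodes, addNode(sp))
      edges <- c(edges, list(addEdge(uk, sp, 1L, "phosphorylation",
                                     "S", 39L)))
      sites <- c(sites, list(addSite(sp, "S", 39L,
                                     if (stabilizes) "stabilizes_protein"
                                     else "destabilizes_protein", uk)))
      stabSign <- ukAct * (if (stabilizes) 1L else -1L)
      pepId <- sprintf("PEP_M2_%s_%d", trt, i)
      m2 <- c(m2, list(data.frame(
        treatment = trt, uk = uk, path = .pathString(pathNodes),
        ukActivity = ukAct, ukSiteFeature = paste0(uk, "_T161"),
        protein = sp, siteRes = "S", sitePos = 39L,
        siteFeature = paste0(sp, "_S39"), stabilizes = stabilizes,
        proteinSign = stabSign, pepId = pepId, pepSign = -stabSign,
        stringsAsFactors = FALSE)))
      labels <- c(labels, list(data.frame(
        peptide_id = pepId, treatment = trt, mechanism = "M2",
        path = .pathString(pathNodes), expected_sign = -stabSign,
        stringsAsFactors = FALSE)))

      ## --- Mechanism 3: transcription-factor control ---
      steps <- 1L + (i %% 3L)
      tf <- sprintf("TF_%s_%d", trt, i)
      pathNodes <- k0; ph <- -1L
      if (steps > 1L) for (s in seq_len(steps - 1L)) {
        im <- sprintf("KM3_%s_%d_%d", trt, i, s)
        e1 <- sample(c(-1L, 1L), 1)
        nodes <- rbind(nodes, addNode(im, kin = TRUE))
        edges <- c(edges, list(addEdge(pathNodes[length(pathNodes)], im, e1)))
        pathNodes <- c(pathNodes, im); ph <- ph * e1
      }
      nodes <- rbind(nodes, addNode(tf, tf = TRUE))
      edges <- c(edges, list(addEdge(pathNodes[length(pathNodes)], tf, 1L,
                                     "phosphorylation", "S", 727L)))
      pathNodes <- c(pathNodes, tf)  # phospho edge carries sign +1
      activates <- runif(1) < 0.7
      sites <- c(sites, list(addSite(tf, "S", 727L,
                                     if (activates) "activates_protein"
                                     else "inhibits_protein",
                                     pathNodes[length(pathNodes) - 1L])))
      act <- ph * (if (activates) 1L else -1L)
      for (j in seq_len(cfg$targetsPerTF)) {
        tg <- sprintf("TG_%s_%d_%d", trt, i, j)
        r <- sample(c(-1L, 1L), 1)
        nodes <- rbind(nodes, addNode(tg))
        edges <- c(edges, list(addEdge(tf, tg, r, "transcriptional")))
        tfTargets <- c(tfTargets, list(data.frame(
          tf_id = tf, target_id = tg, regulation_sign = r,
          stringsAsFactors = FALSE)))
        pepId <- sprintf("PEP_M3_%s_%d_%d", trt, i, j)
        m3 <- c(m3, list(data.frame(
          treatment = trt, tf = tf, path = .pathString(pathNodes),
          phSign = ph, activates = activates, activity = act,
          tfSiteFeature = paste0(tf, "_S727"),
          target = tg, regSign = r, protSign = act * r,
          pepId = pepId, pepSign = act * r, stringsAsFactors = FALSE)))
        labels <- c(labels, list(data.frame(
          peptide_id = pepId, treatment = trt, mechanism = "M3",
          path = .pathString(pathNodes), expected_sign = act * r,
          stringsAsFactors = FALSE)))
      }
    }
  }

  ## decoy TFs: drug-reachable, annotated, but with no planted effect
  decoys <- list()
  for (k in seq_len(cfg$nDecoyTFs)) {
    tf <- sprintf("TFDEC_%d", k)
    src <- ik[1 + ((k - 1) %% length(ik))]
    nodes <- rbind(nodes, addNode(tf, tf = TRUE))
    edges <- c(edges, list(addEdge(src, tf, sample(c(-1L, 1L), 1))))
    sites <- c(sites, list(addSite(tf, "S", 100L, "activates_protein", src)))
    for (j in 1:3) {
      tg <- sprintf("TGDEC_%d_%d", k, j)
      r <- sample(c(-1L, 1L), 1)
      nodes <- rbind(nodes, addNode(tg))
      edges <- c(edges, list(addEdge(tf, tg, r, "transcriptional")))
      tfTargets <- c(tfTargets, list(data.frame(
        tf_id = tf, target_id = tg, regulation_sign = r,
        stringsAsFactors = FALSE)))
      decoys <- c(decoys, list(data.frame(
        tf = tf, target = tg, pepId = sprintf("PEP_DEC_%d_%d", k, j),
        stringsAsFactors = FALSE)))
    }
  }

  ## background signaling nodes; a third get a distant route to the target
  ## pathway, two druggable decoys sit at distance >= 3
  nbg <- cfg$nBackgroundNodes
  bg <- sprintf("BGN_%03d", seq_len(nbg))
  nodes <- rbind(nodes, do.call(rbind, lapply(seq_len(nbg), function(i)
    addNode(bg[i], kin = runif(1) < 0.3, tf = runif(1) < 0.1,
            drug = i <= 2))))
  if (nbg >= 4) {
    for (rep in seq_len(max(1L, nbg %/% 3L))) {
      chain <- sample(bg, 3)
      edges <- c(edges, list(
        addEdge(chain[1], chain[2], sample(c(-1L, 1L), 1)),
        addEdge(chain[2], chain[3], sample(c(-1L, 1L), 1)),
        addEdge(chain[3], sample(appm, 1), sample(c(-1L, 1L), 1))))
    }
    for (i in 1:2) {  # druggable decoys, far from the pathway
      chain <- sample(setdiff(bg, bg[1:2]), 2)
      edges <- c(edges, list(
        addEdge(bg[i], chain[1], sample(c(-1L, 1L), 1)),
        addEdge(chain[1], chain[2], sample(c(-1L, 1L), 1))))
    }
    extra <- max(0L, as.integer(1.5 * nbg) - 3L * (nbg %/% 3L))
    for (rep in seq_len(extra)) {
      pair <- sample(bg, 2)
      edges <- c(edges, list(addEdge(pair[1], pair[2],
                                     sample(c(-1L, 1L), 1))))
    }
  }

  edges <- do.call(rbind, edges)
  edges <- edges[!duplicated(edges[, c("source", "target", "edge_type")]), ]
  sites <- do.call(rbind, sites)
  sites <- sites[!duplicated(sites[, c("protein_id", "residue",
                                       "position")]), ]
  net <- CausalNetwork(nodes = nodes, edges = edges)
  validObject(net)

  list(network = net,
       siteAnnotations = sites,
       tfTargets = do.call(rbind, tfTargets),
       inhibitorMap = inhibitorMap,
       design = design,
       truth = list(mechanismLabels = do.call(rbind, labels),
                    candidateKinases = ik),
       motifs = list(m1 = do.call(rbind, m1), m2 = do.call(rbind, m2),
                     m3 = do.call(rbind, m3),
                     decoys = do.call(rbind, decoys)))
}

#' Simulate the four omic intensity layers with planted effects
#'
#' Draws one log2 baseline per feature from
#' `Normal(baselineLog2Mean, baselineLog2Sd)` and replicate values as
#' baseline + condition effect + `Normal(0, replicateNoiseSd)`. Planted
#' effects have magnitude `plantedEffectLog2` and the sign dictated by sign
#' propagation through the motif, so mechanism consistency holds by
#' construction: upstream-kinase activation-site phosphosites follow kinase
#' activity, stability-site phosphorylation moves the source protein with
#' the site's functional effect and its peptides against it, and TF targets
#' follow TF activity times the regulation sign. A subset of background
#' peptides is designated as planted tumor-associated antigens; half of
#' them additionally receive an upward effect under one treatment (the
#' planted putative TAAs).
#'
#' @param netArt output of [generateCausalNetwork()].
#' @param cfg the [simulationConfig()] used to generate `netArt`.
#' @return a list with `layers` (named list of four [OmicsLayer-class],
#'   log2 scale, no missingness yet), `annotations` (feature annotation
#'   data.frame) and `truth` (completed ground truth).
#' @export
simulateOmicsLayers <- function(netArt, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(deriveSeed(cfg$rngSeed, 2L), .simulateOmicsLayers(netArt, cfg))
}

.simulateOmicsLayers <- function(netArt, cfg) {
  design <- netArt$design
  trts <- treatments(design)
  mo <- netArt$motifs

  bgp <- sprintf("BGP_%04d", seq_len(cfg$nBackgroundProteins))
  cta <- sprintf("CTA_%02d", seq_len(cfg$nCTAProteins))

  ## ---- immunopeptidome features ----
  pepBg <- sprintf("PEP_BG_%04d", seq_len(cfg$nBackgroundPeptides))
  pepSrc <- sample(bgp, cfg$nBackgroundPeptides, replace = TRUE)
  # CTA-derived peptides: reassign one background peptide per CTA protein
  ctaIdx <- sample(cfg$nBackgroundPeptides, cfg$nCTAProteins)
  pepSrc[ctaIdx] <- cta
  # planted TAAs drawn from the remaining background peptides
  taaIdx <- sample(setdiff(seq_len(cfg$nBackgroundPeptides), ctaIdx),
                   cfg$nPlantedTAAs)
  pepIds <- c(pepBg, mo$m2$pepId, mo$m3$pepId, mo$decoys$pepId)
  pepSrcAll <- c(pepSrc, mo$m2$protein, mo$m3$target, mo$decoys$target)
  pepSeq <- .randomPeptides(length(pepIds))

  ## ---- phospho-immunopeptidome features ----
  phpBg <- sprintf("PHP_BG_%03d", seq_len(cfg$nBackgroundPhosphoPeptides))
  phpBgProt <- sample(bgp, cfg$nBackgroundPhosphoPeptides, replace = TRUE)
  phpBgPos <- 400L + seq_len(cfg$nBackgroundPhosphoPeptides)
  phpIds <- c(mo$m1$pepId, phpBg)
  phpSeq <- .randomPeptides(length(phpIds))

  ## ---- proteome features ----
  protIds <- c(mo$m2$protein, unique(mo$m3$target),
               unique(mo$decoys$target), cta, bgp)

  ## ---- phosphoproteome features ----
  bgSiteProt <- sample(bgp, cfg$nBackgroundPhosphosites, replace = TRUE)
  bgSitePos <- 500L + seq_len(cfg$nBackgroundPhosphosites)
  bgSiteIds <- paste0(bgSiteProt, "_S", bgSitePos)
  phosIds <- unique(c(mo$m1$ukSiteFeature, mo$m2$ukSiteFeature,
                      mo$m2$siteFeature, unique(mo$m3$tfSiteFeature),
                      bgSiteIds))

  ## ---- planted effects ledger ----
  eff <- cfg$plantedEffectLog2
  pe <- rbind(
    data.frame(layer = "phospho_immunopeptidome", feature_id = mo$m1$pepId,
               treatment = mo$m1$treatment,
               true_log2FC = eff * mo$m1$pepSign, stringsAsFactors = FALSE),
    data.frame(layer = "phosphoproteome", feature_id = mo$m1$ukSiteFeature,
               treatment = mo$m1$treatment,
               true_log2FC = eff * mo$m1$ukActivity,
               stringsAsFactors = FALSE),
    data.frame(layer = "phosphoproteome", feature_id = mo$m2$ukSiteFeature,
               treatment = mo$m2$treatment,
               true_log2FC = eff * mo$m2$ukActivity,
               stringsAsFactors = FALSE),
    data.frame(layer = "phosphoproteome", feature_id = mo$m2$siteFeature,
               treatment = mo$m2$treatment,
               true_log2FC = eff * mo$m2$ukActivity,
               stringsAsFactors = FALSE),
    data.frame(layer = "proteome", feature_id = mo$m2$protein,
               treatment = mo$m2$treatment,
               true_log2FC = eff * mo$m2$proteinSign,
               stringsAsFactors = FALSE),
    data.frame(layer = "immunopeptidome", feature_id = mo$m2$pepId,
               treatment = mo$m2$treatment,
               true_log2FC = eff * mo$m2$pepSign, stringsAsFactors = FALSE),
    data.frame(layer = "phosphoproteome",
               feature_id = mo$m3$tfSiteFeature, treatment = mo$m3$treatment,
               true_log2FC = eff * mo$m3$phSign, stringsAsFactors = FALSE),
    data.frame(layer = "proteome", feature_id = mo$m3$target,
               treatment = mo$m3$treatment,
               true_log2FC = eff * mo$m3$protSign, stringsAsFactors = FALSE),
    data.frame(layer = "immunopeptidome", feature_id = mo$m3$pepId,
               treatment = mo$m3$treatment,
               true_log2FC = eff * mo$m3$pepSign, stringsAsFactors = FALSE))
  pe <- pe[!duplicated(pe[, c("layer", "feature_id", "treatment")]), ]

  # planted putative TAAs: upward effect under one treatment
  putIdx <- taaIdx[seq_len(ceiling(length(taaIdx) / 2))]
  putTrt <- sample(trts, length(putIdx), replace = TRUE)
  pe <- rbind(pe, data.frame(
    layer = "immunopeptidome", feature_id = pepBg[putIdx],
    treatment = putTrt, true_log2FC = eff, stringsAsFactors = FALSE))

  ## ---- draw the matrices ----
  drawLayer <- function(ids, layer) {
    n <- length(ids)
    base <- rnorm(n, cfg$baselineLog2Mean, cfg$baselineLog2Sd)
    m <- matrix(rep(base, length(design@sampleIds)), nrow = n,
                dimnames = list(ids, design@sampleIds))
    pl <- pe[pe$layer == layer, , drop = FALSE]
    for (r in seq_len(nrow(pl))) {
      ridx <- match(pl$feature_id[r], ids)
      cidx <- which(design@condition == pl$treatment[r])
      m[ridx, cidx] <- m[ridx, cidx] + pl$true_log2FC[r]
    }
    if (cfg$replicateNoiseSd > 0)
      m <- m + matrix(rnorm(length(m), 0, cfg$replicateNoiseSd), nrow = n)
    OmicsLayer(m, layer = layer, design = design, scale = "log2")
  }
  layers <- list(
    immunopeptidome = drawLayer(pepIds, "immunopeptidome"),
    phospho_immunopeptidome = drawLayer(phpIds, "phospho_immunopeptidome"),
    proteome = drawLayer(protIds, "proteome"),
    phosphoproteome = drawLayer(phosIds, "phosphoproteome"))

  ## ---- feature annotations ----
  ann <- rbind(
    data.frame(feature_id = pepIds, feature_kind = "hla_peptide",
               peptide_sequence = pepSeq, source_protein = pepSrcAll,
               site_protein = NA_character_, site_residue = NA_character_,
               site_position = NA_integer_, stringsAsFactors = FALSE),
    data.frame(feature_id = phpIds, feature_kind = "phospho_hla_peptide",
               peptide_sequence = phpSeq,
               source_protein = c(mo$m1$srcProtein, phpBgProt),
               site_protein = c(mo$m1$srcProtein, phpBgProt),
               site_residue = c(mo$m1$siteRes,
                                rep("S", length(phpBg))),
               site_position = c(mo$m1$sitePos, phpBgPos),
               stringsAsFactors = FALSE),
    data.frame(feature_id = protIds, feature_kind = "protein",
               peptide_sequence = NA_character_, source_protein = protIds,
               site_protein = NA_character_, site_residue = NA_character_,
               site_position = NA_integer_, stringsAsFactors = FALSE),
    data.frame(feature_id = phosIds, feature_kind = "phosphosite",
               peptide_sequence = NA_character_,
               source_protein = sub("_[STY][0-9]+$", "", phosIds),
               site_protein = sub("_[STY][0-9]+$", "", phosIds),
               site_residue = sub("^.*_([STY])[0-9]+$", "\\1", phosIds),
               site_position = as.integer(sub("^.*_[STY]", "", phosIds)),
               stringsAsFactors = FALSE))
  ann$immunogenicity_score <- NA_real_
  isPep <- ann$feature_kind == "hla_peptide"
  ann$immunogenicity_score[isPep] <- round(runif(sum(isPep)), 3)

  ## background phospho-HLA sites and a few background stability sites,
  ## all with drug-unreachable upstream kinases
  bgKin <- networkNodes(netArt$network)
  bgKin <- bgKin$id[bgKin$is_kinase & startsWith(bgKin$id, "BGN_")]
  if (!length(bgKin)) bgKin <- "BGN_NONE"
  extraSites <- data.frame(
    protein_id = phpBgProt, residue = "S", position = phpBgPos,
    functional_effect = "activates_protein",
    upstream_kinases = sample(bgKin, length(phpBg), replace = TRUE),
    stringsAsFactors = FALSE)
  taaSrc <- pepSrcAll[taaIdx]
  stabPool <- setdiff(bgp, c(taaSrc, phpBgProt))
  nStab <- min(20L, length(stabPool))
  if (nStab > 0) {
    stabProt <- sample(stabPool, nStab)
    extraSites <- rbind(extraSites, data.frame(
      protein_id = stabProt, residue = "S", position = 77L,
      functional_effect = sample(c("stabilizes_protein",
                                   "destabilizes_protein"), nStab,
                                 replace = TRUE),
      upstream_kinases = sample(bgKin, nStab, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  sites <- rbind(netArt$siteAnnotations, extraSites)
  sites <- sites[!duplicated(sites[, c("protein_id", "residue",
                                       "position")]), ]

  truth <- netArt$truth
  truth$plantedEffects <- pe
  truth$plantedTAAs <- pepSeq[taaIdx]
  truth$plantedPutativeTAAs <- pepSeq[putIdx]
  truth$plantedCTAProteins <- cta
  truth$ctaPeptides <- pepSeq[ctaIdx]

  list(layers = layers, annotations = ann, siteAnnotations = sites,
       truth = truth)
}

#' Apply intensity-dependent (left-censored) missingness
#'
#' Each cell is set missing independently with probability
#' `missingPMax * sigmoid((missingMidpoint - x) / missingSlope)`: low
#' intensities censor more often, emulating the missing-not-at-random
#' dropout that minimum-probability imputation presumes.
#'
#' @param x an [OmicsLayer-class] on log2 scale.
#' @param cfg a [simulationConfig()]; if `missingMidpoint` is `NULL` the
#'   5th percentile of the matrix is used.
#' @param seed integer seed (default derived from `cfg$rngSeed`).
#' @return the layer with cells set to `NA`.
#' @export
applyMissingness <- function(x, cfg, seed = deriveSeed(cfg$rngSeed, 3L)) {
  stopifnot(is(x, "OmicsLayer"))
  if (intensityScale(x) != "log2")
    stop("missingness model expects a log2-scale matrix")
  if (cfg$missingPMax == 0) return(x)
  m <- intensities(x)
  mid <- cfg$missingMidpoint
  if (is.null(mid)) mid <- quantile(m, 0.05, na.rm = TRUE, names = FALSE)
  withSeed(seed, {
    p <- cfg$missingPMax * plogis((mid - m) / cfg$missingSlope)
    drop <- matrix(runif(length(m)) < p, nrow = nrow(m))
    m[drop] <- NA_real_
  })
  OmicsLayer(m, layer = layerType(x), design = sampleDesign(x),
             scale = "log2")
}

#' Generate cohort / benign presence structure and binder calls
#'
#' Planted tumor-associated antigens are strong or weak binders present in
#' at least one disease-cohort sample and absent from every benign sample;
#' a disjoint decoy set is present in both compartments; cancer-testis
#' antigen peptides are either benign-positive or cohort-negative so they
#' never enter the planted TAA set.
#'
#' @param annotations feature annotation data.frame from
#'   [simulateOmicsLayers()].
#' @param truth the ground-truth list from [simulateOmicsLayers()].
#' @param cfg a [simulationConfig()].
#' @param seed integer seed (default derived from `cfg$rngSeed`).
#' @return a list with `cohortPresence` and `benignPresence` (named integer
#'   vectors keyed by peptide sequence), `ctaProteins`, and `binderTable`
#'   (peptide, allele, binder_class).
#' @export
generateCohortPresence <- function(annotations, truth, cfg,
                                   seed = deriveSeed(cfg$rngSeed, 4L)) {
  withSeed(seed, {
    pep <- annotations[annotations$feature_kind == "hla_peptide", ]
    seqs <- pep$peptide_sequence
    taa <- truth$plantedTAAs
    ctaPep <- truth$ctaPeptides
    alleles <- c("HLA-A02:01", "HLA-A30:01", "HLA-B15:10", "HLA-B18:01",
                 "HLA-C03:04", "HLA-C12:03")

    cls <- sample(c("strong", "weak", "non"), length(seqs), replace = TRUE,
                  prob = c(0.55, 0.40, 0.05))
    names(cls) <- seqs
    cls[taa] <- sample(c("strong", "weak"), length(taa), replace = TRUE,
                       prob = c(0.7, 0.3))
    binder <- data.frame(peptide = seqs,
                         allele = sample(alleles, length(seqs),
                                         replace = TRUE),
                         binder_class = unname(cls[seqs]),
                         stringsAsFactors = FALSE)

    cohort <- stats::setNames(integer(length(seqs)), seqs)
    benign <- stats::setNames(integer(length(seqs)), seqs)
    cohort[taa] <- pmax(1L, rbinom(length(taa), cfg$cohortSize, 0.12))

    rest <- setdiff(seqs, c(taa, ctaPep))
    nDecoy <- min(50L, length(rest))
    decoy <- sample(rest, nDecoy)       # present in both compartments
    cohort[decoy] <- pmax(1L, rbinom(nDecoy, cfg$cohortSize, 0.10))
    benign[decoy] <- pmax(1L, rbinom(nDecoy, cfg$benignSize, 0.15))
    rest2 <- setdiff(rest, decoy)
    nBen <- min(200L, length(rest2))
    benOnly <- sample(rest2, nBen)
    benign[benOnly] <- pmax(1L, rbinom(nBen, cfg$benignSize, 0.2))

    # CTA peptides: roughly half benign-positive, one shared with the
    # cohort, the rest absent from both compartments
    if (length(ctaPep)) {
      nb <- ceiling(length(ctaPep) / 2)
      benCta <- ctaPep[seq_len(nb)]
      benign[benCta] <- pmax(1L, rbinom(nb, cfg$benignSize, 0.25))
      cohort[benCta[1]] <- 1L
    }
    list(cohortPresence = cohort[cohort > 0 | benign > 0 |
                                   seqs %in% taa],
         benignPresence = benign[cohort > 0 | benign > 0 |
                                   seqs %in% taa],
         ctaProteins = truth$plantedCTAProteins,
         binderTable = binder)
  })
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper chaining [generateCausalNetwork()],
#' [simulateOmicsLayers()], [applyMissingness()] on every layer and
#' [generateCohortPresence()], fully deterministic under `cfg$rngSeed`.
#'
#' @param cfg a [simulationConfig()].
#' @param missingness apply the censoring model (default `TRUE`).
#' @return a list with `network`, `siteAnnotations`, `tfTargets`,
#'   `inhibitorMap`, `design`, `layers`, `annotations`, `cohort` (presence
#'   and binder structures) and `truth`.
#' @export
simulateStudy <- function(cfg = simulationConfig(), missingness = TRUE) {
  netArt <- generateCausalNetwork(cfg)
  sim <- simulateOmicsLayers(netArt, cfg)
  layers <- sim$layers
  if (missingness && cfg$missingPMax > 0)
    layers <- lapply(seq_along(layers), function(i)
      applyMissingness(layers[[i]], cfg,
                       seed = deriveSeed(cfg$rngSeed, 30L + i)))
  names(layers) <- names(sim$layers)
  cohort <- generateCohortPresence(sim$annotations, sim$truth, cfg)
  list(network = netArt$network, siteAnnotations = sim$siteAnnotations,
       tfTargets = netArt$tfTargets, inhibitorMap = netArt$inhibitorMap,
       design = netArt$design, layers = layers,
       annotations = sim$annotations, cohort = cohort, truth = sim$truth)
}
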