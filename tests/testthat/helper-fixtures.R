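# shared fixtures, all built in code

toyDesign <- function(conditions = c("control", "imatinib", "PP2",
                                     "SP600125"), replicates = 3L) {
  SampleDesign(conditions, control = "control", replicates = replicates)
}

# a down-scaled synthetic study for fast module tests
smallSimConfig <- function(seed = 1L, ...) {
  simulationConfig(nBackgroundNodes = 30L, nMotifsPerMechanism = 3L,
                   nBackgroundPeptides = 150L,
                   nBackgroundPhosphoPeptides = 10L,
                   nBackgroundProteins = 60L,
                   nBackgroundPhosphosites = 80L,
                   targetsPerTF = 3L, nPlantedTAAs = 8L,
                   nCTAProteins = 5L, rngSeed = seed, ...)
}

# seeded random directed graph as a CausalNetwork (n <= 26 nodes)
randomToyNetwork <- function(seed, n = 10L, p = 0.25) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n)]
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  CausalNetwork(nodes = data.frame(id = ids),
                edges = if (nrow(pairs))
                  data.frame(pairs, sign = sample(c(-1L, 1L), nrow(pairs),
                                                  replace = TRUE))
                else data.frame(source = character(),
                                target = character(), sign = integer()))
}

# independent enumeration oracle for capped simple paths that stop at the
# first target member (igraph enumerator, then interior-target filter)
enumeratePathsOracle <- function(net, node, targetSet, maxLen) {
  g <- igraph::graph_from_data_frame(
    networkEdges(net)[, c("source", "target")], directed = TRUE,
    vertices = networkNodes(net)$id)
  tset <- intersect(unique(targetSet), networkNodes(net)$id)
  total <- 0L
  for (tg in tset) {
    ps <- suppressWarnings(
      igraph::all_simple_paths(g, from = node, to = tg, mode = "out",
                               cutoff = maxLen))
    for (p in ps) {
      nodes <- names(p)
      if (length(nodes) >= 2 &&
          !any(nodes[-c(1, length(nodes))] %in% tset))
        total <- total + 1L
    }
  }
  total
}

# walk a '>'-joined path and verify every hop is a network edge
pathExistsInNetwork <- function(net, pathString) {
  nodes <- strsplit(pathString, ">", fixed = TRUE)[[1]]
  if (length(nodes) < 2) return(nodes %in% networkNodes(net)$id)
  ed <- networkEdges(net)
  all(vapply(seq_len(length(nodes) - 1), function(h)
    any(ed$source == nodes[h] & ed$target == nodes[h + 1]), TRUE))
}

# brute-force differential oracle via stats::t.test per feature
tTestOracle <- function(m, design, varEqual = TRUE) {
  ctrl <- m[, design@condition == controlCondition(design), drop = FALSE]
  out <- list()
  for (trt in treatments(design)) {
    tr <- m[, design@condition == trt, drop = FALSE]
    for (i in seq_len(nrow(m))) {
      tt <- stats::t.test(tr[i, ], ctrl[i, ], var.equal = varEqual)
      out[[length(out) + 1L]] <- data.frame(
        feature_id = rownames(m)[i], treatment = trt,
        log2FC = mean(tr[i, ]) - mean(ctrl[i, ]),
        t_statistic = unname(tt$statistic), p_value = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# minimal one-motif stability fixture for the sign-algebra cases:
# IK -(pathSign)-> UK -(phospho, +1)-> site S39 on protein P, peptide PEP
signFixture <- function(pathSign, stabilizes, observedPep,
                        siteObs = NA, protObs = NA) {
  net <- CausalNetwork(
    nodes = data.frame(id = c("IK", "UK", "P"),
                       is_kinase = c(TRUE, TRUE, FALSE)),
    edges = data.frame(source = c("IK", "UK"), target = c("UK", "P"),
                       sign = c(pathSign, 1L),
                       edge_type = c("other", "phosphorylation"),
                       site_residue = c(NA, "S"),
                       site_position = c(NA, 39L)))
  sites <- data.frame(protein_id = "P", residue = "S", position = 39L,
                      functional_effect = if (stabilizes)
                        "stabilizes_protein" else "destabilizes_protein",
                      upstream_kinases = "UK", stringsAsFactors = FALSE)
  ann <- data.frame(feature_id = "PEP", feature_kind = "hla_peptide",
                    peptide_sequence = "KNITPRKKL", source_protein = "P",
                    site_protein = NA, site_residue = NA,
                    site_position = NA, stringsAsFactors = FALSE)
  mkRes <- function(feature, layer, obs) {
    if (is.na(obs)) return(NULL)
    data.frame(feature_id = feature, layer = layer, treatment = "drug",
               log2FC = 2 * obs, t_statistic = 10 * obs,
               p_value = 1e-6, adj_p_value = 1e-6,
               significant = obs != 0,
               direction = c("down", "none", "up")[obs + 2],
               stringsAsFactors = FALSE)
  }
  list(net = net, sites = sites, ann = ann,
       pepRes = mkRes("PEP", "immunopeptidome", observedPep),
       phosphoRes = mkRes("P_S39", "phosphoproteome", siteObs),
       protRes = mkRes("P", "proteome", protObs),
       map = list(drug = "IK"))
}

# independent brute-force TAA set algebra
bruteTAAs <- function(binders, coh, ben) {
  out <- character(0)
  for (p in unique(toupper(binders))) {
    nc <- if (p %in% names(coh)) coh[[p]] else 0L
    nb <- if (p %in% names(ben)) ben[[p]] else 0L
    if (nc >= 1 && nb == 0) out <- c(out, p)
  }
  sort(out)
}

# seeded toy peptide universe for set-logic property tests
randomUniverse <- function(seed) {
  set.seed(seed)
  peps <- paste0("PEP", sprintf("%03d", 1:60))
  coh <- setNames(rbinom(60, 5, 0.3), peps)
  ben <- setNames(rbinom(60, 5, 0.25), peps)
  binders <- sample(peps, 40)
  list(peps = peps, coh = coh[coh > 0], ben = ben[ben > 0],
       binders = binders)
}
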