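#' Propagate a perturbation sign along a causal path
#'
#' The predicted direction of the terminal entity is the initial
#' perturbation sign (a pharmacologically inhibited kinase starts at -1)
#' times the product of the edge signs along the path. The empty path
#' returns the initial sign (the inhibited kinase itself).
#'
#' @param path a data.frame of contiguous causal edges with columns
#'   `source`, `target`, `sign` (row *i*'s target is row *i+1*'s source);
#'   zero rows = empty path.
#' @param initialSign +1 or -1 (default -1, inhibition).
#' @return +1 or -1.
#' @examples
#' p <- data.frame(source = c("A", "B"), target = c("B", "C"),
#'                 sign = c(1L, 1L))
#' propagatePerturbationSign(p)        # -1: inhibition transmits
#' @export
propagatePerturbationSign <- function(path, initialSign = -1L) {
  stopifnot(initialSign %in% c(-1L, 1L))
  if (is.null(path) || nrow(path) == 0L) return(as.integer(initialSign))
  if (nrow(path) > 1L &&
      !all(path$target[-nrow(path)] == path$source[-1L]))
    stop("non-contiguous causal path")
  as.integer(initialSign * prod(path$sign))
}

# edge rows for a node path (first matching edge per hop)
.pathEdges <- function(net, nodePath) {
  ed <- networkEdges(net)
  if (length(nodePath) < 2L)
    return(ed[0, c("source", "target", "sign"), drop = FALSE])
  rows <- vapply(seq_len(length(nodePath) - 1L), function(h) {
    hit <- which(ed$source == nodePath[h] & ed$target == nodePath[h + 1L])
    if (!length(hit))
      stop("path edge absent from network: ", nodePath[h], " -> ",
           nodePath[h + 1L])
    hit[1]
  }, 1L)
  ed[rows, c("source", "target", "sign"), drop = FALSE]
}

# all shortest directed paths from -> to with <= cap edges, as node-id
# vectors; empty list if unreachable within the cap
.cappedShortestPaths <- function(g, from, to, cap) {
  if (from == to) return(list(from))
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = from, to = to, mode = "out"))
  paths <- lapply(sp$vpaths %||% sp$res, function(p) names(p))
  paths <- paths[lengths(paths) >= 2]
  paths[vapply(paths, length, 1L) - 1L <= cap]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inhibited kinases of a treatment, family-expanded
.inhibitedKinases <- function(net, inhibitorMap, treatment) {
  ids <- inhibitorMap[[treatment]]
  if (is.null(ids)) stop("no inhibited kinases mapped for ", treatment)
  .expandFamily(net, ids)
}

# (feature, treatment) -> +1 / -1 when significant, 0 when measured but
# not significant; absent keys are 'not measured'
.observedSignMap <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    return(stats::setNames(integer(0), character(0)))
  val <- ifelse(results$significant, ifelse(results$log2FC > 0, 1L, -1L), 0L)
  stats::setNames(val, paste(results$feature_id, results$treatment,
                             sep = "\r"))
}

.lookupSign <- function(map, feature, treatment) {
  v <- map[paste(feature, treatment, sep = "\r")]
  if (is.na(v)) NA_integer_ else as.integer(v)
}

# sign of the kinase -> site phosphorylation edge; +1 when no explicit
# site edge is present
.siteEdgeSign <- function(net, kinase, protein, residue, position) {
  ed <- networkEdges(net)
  hit <- which(ed$source == kinase & ed$target == protein &
               ed$edge_type == "phosphorylation" &
               (is.na(ed$site_residue) |
                (ed$site_residue == residue &
                 ed$site_position == position)))
  if (!length(hit))
    hit <- which(ed$source == kinase & ed$target == protein)
  if (length(hit)) as.integer(ed$sign[hit[1]]) else 1L
}

# majority observed sign over a kinase's activation-site phosphosites;
# list(value, flag): value NA = no measured site, 0 = none/tie
.kinaseActivityObservation <- function(kinase, treatment, siteAnnotations,
                                       phosphoObs) {
  s <- siteAnnotations[siteAnnotations$protein_id == kinase &
                       siteAnnotations$functional_effect ==
                         "activates_protein", , drop = FALSE]
  if (nrow(s) == 0) return(list(value = NA_integer_, flag = ""))
  keys <- paste0(s$protein_id, "_", s$residue, s$position)
  obs <- vapply(keys, function(k) {
    v <- .lookupSign(phosphoObs, k, treatment)
    if (is.na(v)) NA_integer_ else v
  }, 1L)
  obs <- obs[!is.na(obs)]
  if (!length(obs)) return(list(value = NA_integer_, flag = ""))
  pos <- sum(obs == 1); neg <- sum(obs == -1)
  if (pos > neg) list(value = 1L, flag = "")
  else if (neg > pos) list(value = -1L, flag = "")
  else list(value = 0L, flag = "activation_site_tie")
}

# verdict under the configured mode; supports is a list of
# c(observed, expected) pairs (observed NA = not measured -> ignored)
.consistencyVerdict <- function(predicted, observed, supports, mode) {
  ok <- !is.na(observed) && observed != 0L && observed == predicted
  for (s in supports) {
    if (is.na(s[1])) next
    if (mode == "strict") {
      if (s[1] != s[2]) ok <- FALSE
    } else {
      if (s[1] != 0L && s[1] != s[2]) ok <- FALSE
    }
  }
  ok
}

.assignmentRow <- function(peptide, treatment, mechanism, pathNodes,
                           entity, site, predicted, observed,
                           supKinase = NA_integer_, supSite = NA_integer_,
                           supProtein = NA_integer_, consistent, mode,
                           flags = "") {
  data.frame(peptide_id = peptide, treatment = treatment,
             mechanism = mechanism, path = .pathString(pathNodes),
             n_steps = length(pathNodes) - 1L, entity = entity,
             site = site, predicted_sign = as.integer(predicted),
             observed_sign = if (is.na(observed)) NA_integer_
                             else as.integer(observed),
             support_kinase_sign = supKinase, support_site_sign = supSite,
             support_protein_sign = supProtein,
             consistent = consistent, mode = mode, flags = flags,
             stringsAsFactors = FALSE)
}

.emptyAssignments <- function() {
  .assignmentRow("x", "x", "M1", c("a", "b"), "x", "x", 1L, 1L,
                 consistent = TRUE, mode = "lenient")[0, ]
}

#' Mechanism 1: direct phosphorylation of presented peptides
#'
#' For every significantly modulated phosphorylated HLA-I peptide, looks up
#' the annotated upstream kinases of its phosphosite, extracts all shortest
#' causal paths (at most `m1MaxSteps` edges) from the treatment's inhibited
#' kinases to each upstream kinase, propagates the inhibition sign along
#' each path to predict the peptide's direction, and compares it with the
#' observation. The upstream kinase's activity is independently supported
#' by the majority sign of its activation-site phosphosites in the
#' phosphoproteome when measured.
#'
#' @param ppepResults [differentialTest()] output for the
#'   phospho-immunopeptidome layer.
#' @param annotations feature annotation data.frame (carries each
#'   phospho-peptide's site).
#' @param siteAnnotations phosphosite functional annotation data.frame.
#' @param network a [CausalNetwork-class].
#' @param inhibitorMap named list treatment -> inhibited kinase ids.
#' @param phosphoResults [differentialTest()] output for the
#'   phosphoproteome layer (may be `NULL`).
#' @param cfg an [analysisConfig()].
#' @return a data.frame of mechanism assignments, one row per
#'   (peptide, treatment, path); `attr(, "skipped")` counts peptides
#'   without a usable site annotation.
#' @export
assignMechanism1 <- function(ppepResults, annotations, siteAnnotations,
                             network, inhibitorMap, phosphoResults = NULL,
                             cfg = analysisConfig()) {
  g <- .asIgraph(network)
  phosphoObs <- .observedSignMap(phosphoResults)
  pepObs <- .observedSignMap(ppepResults)
  sig <- ppepResults[ppepResults$significant, , drop = FALSE]
  rows <- list(); skipped <- 0L
  nodeIds <- networkNodes(network)$id
  for (i in seq_len(nrow(sig))) {
    pep <- sig$feature_id[i]; trt <- sig$treatment[i]
    ann <- annotations[annotations$feature_id == pep, , drop = FALSE]
    if (nrow(ann) == 0 || is.na(ann$site_protein[1])) {
      skipped <- skipped + 1L; next
    }
    sp <- ann$site_protein[1]; res <- ann$site_residue[1]
    pos <- ann$site_position[1]
    sa <- siteAnnotations[siteAnnotations$protein_id == sp &
                          siteAnnotations$residue == res &
                          siteAnnotations$position == pos, , drop = FALSE]
    uks <- if (nrow(sa)) unlist(strsplit(sa$upstream_kinases[1], ","))
           else character(0)
    uks <- uks[nzchar(uks)]
    if (!length(uks)) { skipped <- skipped + 1L; next }
    iks <- intersect(.inhibitedKinases(network, inhibitorMap, trt), nodeIds)
    observed <- .lookupSign(pepObs, pep, trt)
    for (uk in uks) {
      if (!uk %in% nodeIds) next
      sup <- .kinaseActivityObservation(uk, trt, siteAnnotations, phosphoObs)
      es <- .siteEdgeSign(network, uk, sp, res, pos)
      for (ik in iks) {
        paths <- .cappedShortestPaths(g, ik, uk, cfg$m1MaxSteps)
        for (p in paths) {
          ukAct <- propagatePerturbationSign(.pathEdges(network, p))
          predicted <- ukAct * es
          ok <- .consistencyVerdict(predicted, observed,
                                    list(c(sup$value, ukAct)),
                                    cfg$consistencyMode)
          rows <- c(rows, list(.assignmentRow(
            pep, trt, "M1", p, uk, paste0(sp, "_", res, pos), predicted,
            observed, supKinase = sup$value, consistent = ok,
            mode = cfg$consistencyMode, flags = sup$flag)))
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .emptyAssignments()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Mechanism 2: phosphorylation-dependent source-protein stability
#'
#' For every significantly modulated HLA-I peptide whose source protein
#' carries a stability-regulating phosphosite: the inhibition sign is
#' propagated from the inhibited kinases to the site's upstream kinase
#' (paths of at most `m2MaxSteps` edges), the site's phosphorylation
#' follows the kinase activity, protein stability follows the site's
#' functional effect (stabilizing: same sign; destabilizing: opposite), the
#' source-protein abundance follows stability, and peptide supply moves
#' against stability (a more stable protein is degraded less, so fewer
#' peptides are produced).
#'
#' @param pepResults [differentialTest()] output for the immunopeptidome.
#' @param annotations feature annotation data.frame.
#' @param siteAnnotations phosphosite functional annotations.
#' @param network a [CausalNetwork-class].
#' @param inhibitorMap named list treatment -> inhibited kinase ids.
#' @param phosphoResults,proteinResults [differentialTest()] outputs for
#'   the phosphoproteome and proteome (either may be `NULL`).
#' @param cfg an [analysisConfig()].
#' @return a data.frame of mechanism assignments; `attr(, "skipped")`
#'   counts stability sites without an annotated upstream kinase.
#' @export
assignMechanism2 <- function(pepResults, annotations, siteAnnotations,
                             network, inhibitorMap, phosphoResults = NULL,
                             proteinResults = NULL,
                             cfg = analysisConfig()) {
  g <- .asIgraph(network)
  phosphoObs <- .observedSignMap(phosphoResults)
  protObs <- .observedSignMap(proteinResults)
  pepObs <- .observedSignMap(pepResults)
  sig <- pepResults[pepResults$significant, , drop = FALSE]
  stab <- siteAnnotations[siteAnnotations$functional_effect %in%
                            c("stabilizes_protein", "destabilizes_protein"),
                          , drop = FALSE]
  rows <- list(); skipped <- 0L
  nodeIds <- networkNodes(network)$id
  for (i in seq_len(nrow(sig))) {
    pep <- sig$feature_id[i]; trt <- sig$treatment[i]
    ann <- annotations[annotations$feature_id == pep, , drop = FALSE]
    if (nrow(ann) == 0) next
    src <- ann$source_protein[1]
    ss <- stab[stab$protein_id == src, , drop = FALSE]
    if (nrow(ss) == 0) next
    iks <- intersect(.inhibitedKinases(network, inhibitorMap, trt), nodeIds)
    observed <- .lookupSign(pepObs, pep, trt)
    for (j in seq_len(nrow(ss))) {
      effDir <- if (ss$functional_effect[j] == "stabilizes_protein") 1L
                else -1L
      uks <- unlist(strsplit(ss$upstream_kinases[j], ","))
      uks <- uks[nzchar(uks)]
      if (!length(uks)) { skipped <- skipped + 1L; next }
      siteKey <- paste0(src, "_", ss$residue[j], ss$position[j])
      supSite <- .lookupSign(phosphoObs, siteKey, trt)
      supProt <- .lookupSign(protObs, src, trt)
      for (uk in uks) {
        if (!uk %in% nodeIds) next
        es <- .siteEdgeSign(network, uk, src, ss$residue[j],
                            ss$position[j])
        for (ik in iks) {
          paths <- .cappedShortestPaths(g, ik, uk, cfg$m2MaxSteps)
          for (p in paths) {
            ukAct <- propagatePerturbationSign(.pathEdges(network, p))
            siteSign <- ukAct * es
            stabSign <- siteSign * effDir
            predicted <- -stabSign
            ok <- .consistencyVerdict(
              predicted, observed,
              list(c(supSite, siteSign), c(supProt, stabSign)),
              cfg$consistencyMode)
            rows <- c(rows, list(.assignmentRow(
              pep, trt, "M2", p, uk, siteKey, predicted, observed,
              supSite = supSite, supProtein = supProt,
              consistent = ok, mode = cfg$consistencyMode)))
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .emptyAssignments()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Mechanism 3: transcription-factor control of source proteins
#'
#' For every transcription factor reachable from a treatment's inhibited
#' kinases within `m3MaxSteps` edges: the propagated sign gives the TF's
#' activity-site phosphorylation, the site's functional effect converts it
#' to TF activity (activating site: same sign; inhibitory site: flipped; no
#' annotated activity site: propagation alone, flagged), and each signed
#' TF-target edge predicts the target protein and its presented peptides.
#' Assignments are emitted for significantly modulated peptides of target
#' source proteins, with TF-site phosphorylation and target-protein
#' abundance as supporting observations.
#'
#' @param pepResults [differentialTest()] output for the immunopeptidome.
#' @param proteinResults,phosphoResults [differentialTest()] outputs for
#'   the proteome and phosphoproteome (either may be `NULL`).
#' @param tfTargets TF-target data.frame (`tf_id`, `target_id`,
#'   `regulation_sign`).
#' @param annotations feature annotation data.frame.
#' @param siteAnnotations phosphosite functional annotations.
#' @param network a [CausalNetwork-class].
#' @param inhibitorMap named list treatment -> inhibited kinase ids.
#' @param cfg an [analysisConfig()].
#' @return a data.frame of mechanism assignments.
#' @export
assignMechanism3 <- function(pepResults, proteinResults = NULL,
                             phosphoResults = NULL, tfTargets,
                             annotations, siteAnnotations, network,
                             inhibitorMap, cfg = analysisConfig()) {
  g <- .asIgraph(network)
  phosphoObs <- .observedSignMap(phosphoResults)
  protObs <- .observedSignMap(proteinResults)
  pepObs <- .observedSignMap(pepResults)
  sig <- pepResults[pepResults$significant, , drop = FALSE]
  nodeIds <- networkNodes(network)$id
  rows <- list()
  trts <- intersect(unique(pepResults$treatment), names(inhibitorMap))
  for (tf in intersect(unique(tfTargets$tf_id), nodeIds)) {
    acts <- siteAnnotations[siteAnnotations$protein_id == tf &
                            siteAnnotations$functional_effect %in%
                              c("activates_protein", "inhibits_protein"),
                            , drop = FALSE]
    hasSite <- nrow(acts) > 0
    siteDir <- if (hasSite && acts$functional_effect[1] ==
                 "inhibits_protein") -1L else 1L
    siteKey <- if (hasSite)
      paste0(tf, "_", acts$residue[1], acts$position[1]) else NA_character_
    targets <- tfTargets[tfTargets$tf_id == tf, , drop = FALSE]
    for (trt in trts) {
      iks <- intersect(.inhibitedKinases(network, inhibitorMap, trt),
                       nodeIds)
      supSite <- if (hasSite) .lookupSign(phosphoObs, siteKey, trt)
                 else NA_integer_
      for (ik in iks) {
        paths <- .cappedShortestPaths(g, ik, tf, cfg$m3MaxSteps)
        for (p in paths) {
          ph <- propagatePerturbationSign(.pathEdges(network, p))
          act <- ph * siteDir
          for (j in seq_len(nrow(targets))) {
            tg <- targets$target_id[j]
            predProt <- act * as.integer(targets$regulation_sign[j])
            peps <- annotations$feature_id[
              annotations$feature_kind == "hla_peptide" &
              annotations$source_protein == tg]
            peps <- intersect(peps, sig$feature_id[sig$treatment == trt])
            if (!length(peps)) next
            supProt <- .lookupSign(protObs, tg, trt)
            for (pep in peps) {
              observed <- .lookupSign(pepObs, pep, trt)
              ok <- .consistencyVerdict(
                predProt, observed,
                list(c(supSite, ph), c(supProt, predProt)),
                cfg$consistencyMode)
              rows <- c(rows, list(.assignmentRow(
                pep, trt, "M3", p, tf,
                if (hasSite) siteKey else "", predProt, observed,
                supSite = supSite, supProtein = supProt,
                consistent = ok, mode = cfg$consistencyMode,
                flags = if (hasSite) "" else "no_activity_site")))
            }
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .emptyAssignments()
  rownames(out) <- NULL
  out
}

#' Score mechanism recovery against the planted ground truth
#'
#' A (peptide, treatment, mechanism) triple counts as predicted when at
#' least one of its assignment rows is consistent; it is a true positive
#' iff the triple is among the generator's planted mechanism labels.
#' Precision with zero predictions is reported as 1 with a flag.
#'
#' @param assignments rbind of the `assignMechanism*()` outputs.
#' @param truth a ground-truth list with a `mechanismLabels` data.frame.
#' @return a list with `overall` (precision, recall, f1, tp, fp, fn),
#'   `perMechanism` (one row per mechanism) and `flag`.
#' @export
evaluateRecovery <- function(assignments, truth) {
  lab <- truth$mechanismLabels
  truthKeys <- unique(paste(lab$peptide_id, lab$treatment, lab$mechanism,
                            sep = "\r"))
  cons <- assignments[assignments$consistent, , drop = FALSE]
  predKeys <- unique(paste(cons$peptide_id, cons$treatment, cons$mechanism,
                           sep = "\r"))
  score <- function(pred, tru) {
    tp <- length(intersect(pred, tru))
    fp <- length(setdiff(pred, tru))
    fn <- length(setdiff(tru, pred))
    precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
    recall <- if (length(tru) == 0) 1 else tp / length(tru)
    f1 <- if (precision + recall == 0) 0
          else 2 * precision * recall / (precision + recall)
    c(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
      f1 = f1)
  }
  mechs <- c("M1", "M2", "M3")
  per <- do.call(rbind, lapply(mechs, function(mm) {
    tru <- truthKeys[grepl(paste0("\r", mm, "$"), truthKeys)]
    pred <- predKeys[grepl(paste0("\r", mm, "$"), predKeys)]
    data.frame(mechanism = mm, n_truth = length(tru),
               n_predicted = length(pred), t(score(pred, tru)),
               stringsAsFactors = FALSE)
  }))
  ov <- score(predKeys, truthKeys)
  list(overall = as.list(ov),
       perMechanism = per,
       flag = if (length(predKeys) == 0) "no_predictions" else "")
}
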