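#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> impute -> differential
#' -> proximity -> mechanisms -> antigens as one reproducible run. A single
#' seed is fanned out to per-stage child seeds by stable derivation, so
#' rerunning with the same configuration and seed reproduces byte-identical
#' outputs. All intermediate tables are materialized in `outDir` together
#' with a JSON manifest (configuration echo, seed, per-table row counts and
#' md5 digests).
#'
#' @param outDir output directory.
#' @param cfg an [analysisConfig()].
#' @param simCfg a [simulationConfig()] (synthetic mode); its `rngSeed` is
#'   overridden by `seed`.
#' @param seed integer run seed.
#' @param inputs `NULL` for synthetic mode, or a named list of file paths
#'   (`immunopeptidome`, `phospho_immunopeptidome`, `proteome`,
#'   `phosphoproteome`, `network_edges`, `network_nodes`, `sites`,
#'   `tf_targets`, `inhibitor_map`, `targets`, `binders`, `cohort`,
#'   `benign`, `cta`) plus a `design` [SampleDesign-class]; any missing
#'   path aborts the run with the stage and input named.
#' @param missingness apply the censoring model in synthetic mode.
#' @return invisibly, a list with the stage outputs (`layers`, `results`,
#'   `proximity`, `assignments`, `recovery` in synthetic mode, `antigens`)
#'   and the written `manifest`.
#' @export
runPipeline <- function(outDir, cfg = analysisConfig(),
                        simCfg = simulationConfig(), seed = cfg$rngSeed,
                        inputs = NULL, missingness = TRUE) {
  stage <- "setup"
  fail <- function(e) {
    try(writeResultsBundle(list(), file.path(outDir, "failure"),
                           config = cfg, seed = seed), silent = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (is.null(inputs)) {
      stage <- "simulate"
      simCfg$rngSeed <- as.integer(seed)
      study <- simulateStudy(simCfg, missingness = missingness)
    } else {
      stage <- "load"
      study <- .loadStudyInputs(inputs)
    }

    stage <- "preprocess"
    layers <- lapply(study$layers, log2AndFilter, cfg = cfg)
    stage <- "impute"
    layers <- lapply(seq_along(layers), function(i)
      imputeMinProb(layers[[i]], cfg, seed = deriveSeed(seed, 40L + i)))
    names(layers) <- names(study$layers)

    stage <- "differential"
    results <- lapply(layers, differentialTest, cfg = cfg)

    stage <- "proximity"
    nd <- networkNodes(study$network)
    targetSet <- nd$id[nd$in_target_pathway]
    prox <- if (length(targetSet))
      proximityTable(study$network, targetSet, cfg) else NULL
    candidates <- if (!is.null(prox)) selectCandidateKinases(prox)
                  else character(0)

    stage <- "mechanisms"
    a1 <- assignMechanism1(results$phospho_immunopeptidome,
                           study$annotations, study$siteAnnotations,
                           study$network, study$inhibitorMap,
                           results$phosphoproteome, cfg)
    a2 <- assignMechanism2(results$immunopeptidome, study$annotations,
                           study$siteAnnotations, study$network,
                           study$inhibitorMap, results$phosphoproteome,
                           results$proteome, cfg)
    a3 <- assignMechanism3(results$immunopeptidome, results$proteome,
                           results$phosphoproteome, study$tfTargets,
                           study$annotations, study$siteAnnotations,
                           study$network, study$inhibitorMap, cfg)
    assignments <- rbind(a1, a2, a3)

    stage <- "antigens"
    binders <- binderPeptides(study$cohort$binderTable,
                              strongOnly = cfg$strongBindersOnly)
    taa <- identifyTAAs(binders, study$cohort$cohortPresence,
                        study$cohort$benignPresence)
    putative <- selectPutativeTAAs(taa, results$immunopeptidome,
                                   study$annotations)
    cta <- ctaCrosstab(study$annotations, study$cohort$ctaProteins,
                       study$cohort$cohortPresence,
                       study$cohort$benignPresence)
    taaReport <- taaModulationReport(taa, results$immunopeptidome,
                                     study$annotations,
                                     study$cohort$binderTable)

    recovery <- NULL
    if (!is.null(study$truth)) {
      stage <- "recovery"
      recovery <- evaluateRecovery(assignments, study$truth)
    }

    stage <- "write"
    counts <- summarizeCounts(do.call(rbind, results))
    bundle <- list(differential = do.call(rbind, results),
                   differential_counts = counts,
                   proximity = prox,
                   candidate_kinases = data.frame(node_id = candidates,
                                                  stringsAsFactors = FALSE),
                   mechanism_assignments = assignments,
                   taa_set = data.frame(peptide = taa,
                                        stringsAsFactors = FALSE),
                   putative_taas = data.frame(peptide = putative,
                                              stringsAsFactors = FALSE),
                   cta_crosstab = cta,
                   taa_modulation = taaReport)
    if (!is.null(recovery))
      bundle$mechanism_recovery <-
        cbind(data.frame(scope = c(recovery$perMechanism$mechanism,
                                   "overall"), stringsAsFactors = FALSE),
              rbind(recovery$perMechanism[, c("n_truth", "n_predicted",
                                              "tp", "fp", "fn",
                                              "precision", "recall",
                                              "f1")],
                    data.frame(n_truth = sum(recovery$perMechanism$n_truth),
                               n_predicted =
                                 sum(recovery$perMechanism$n_predicted),
                               t(vapply(c("tp", "fp", "fn", "precision",
                                          "recall", "f1"),
                                        function(k) recovery$overall[[k]],
                                        1.0)))))
    bundle <- bundle[!vapply(bundle, is.null, TRUE)]
    manifest <- writeResultsBundle(bundle, outDir, config = cfg,
                                   seed = seed)
    invisible(list(layers = layers, results = results, proximity = prox,
                   candidates = candidates, assignments = assignments,
                   antigens = list(taaSet = taa, putative = putative,
                                   ctaTable = cta, report = taaReport),
                   recovery = recovery, truth = study$truth,
                   manifest = manifest))
  }, error = fail)
}

# load a file-mode study; every required path must exist
.loadStudyInputs <- function(inputs) {
  req <- c("immunopeptidome", "phospho_immunopeptidome", "proteome",
           "phosphoproteome", "network_edges", "network_nodes", "sites",
           "tf_targets", "inhibitor_map", "binders", "cohort", "benign",
           "design")
  missing <- setdiff(req, names(inputs))
  if (length(missing))
    stop("missing input(s): ", paste(missing, collapse = ", "))
  paths <- inputs[setdiff(req, "design")]
  bad <- names(paths)[!vapply(paths, file.exists, TRUE)]
  if (length(bad))
    stop("input file(s) not found: ",
         paste(paste0(bad, " (", unlist(paths[bad]), ")"), collapse = ", "))
  design <- inputs$design
  layers <- list(
    immunopeptidome = readIntensityMatrix(inputs$immunopeptidome,
                                          "immunopeptidome", design,
                                          scale = "log2"),
    phospho_immunopeptidome =
      readIntensityMatrix(inputs$phospho_immunopeptidome,
                          "phospho_immunopeptidome", design,
                          scale = "log2"),
    proteome = readIntensityMatrix(inputs$proteome, "proteome", design,
                                   scale = "log2"),
    phosphoproteome = readIntensityMatrix(inputs$phosphoproteome,
                                          "phosphoproteome", design,
                                          scale = "log2"))
  ann <- if (!is.null(inputs$annotations)) .readTsv(inputs$annotations)
         else NULL
  binder <- readBinderTable(inputs$binders)
  list(layers = layers,
       network = readCausalNetwork(inputs$network_edges,
                                   inputs$network_nodes),
       siteAnnotations = readSiteAnnotations(inputs$sites),
       tfTargets = readTFTargets(inputs$tf_targets),
       inhibitorMap = readInhibitorMap(inputs$inhibitor_map),
       annotations = ann, design = design,
       cohort = list(cohortPresence = readPresenceCounts(inputs$cohort),
                     benignPresence = readPresenceCounts(inputs$benign),
                     ctaProteins = if (!is.null(inputs$cta))
                       readPeptideList(inputs$cta) else character(0),
                     binderTable = binder),
       truth = NULL)
}

#' Write every synthetic-study input artifact to a directory
#'
#' Materializes the generator output in the TSV dialects read back by the
#' file-mode pipeline: the four intensity matrices, the network edge and
#' node tables, site annotations, TF targets, the inhibitor map, binder
#' calls, presence counts, the CTA protein list, feature annotations and a
#' ground-truth JSON.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory.
#' @return invisibly, the named vector of written paths.
#' @export
writeStudyInputs <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  for (nm in names(study$layers))
    writeIntensityMatrix(study$layers[[nm]], p(paste0(nm, ".tsv")))
  writeCausalNetwork(study$network, p("network_edges.tsv"),
                     p("network_nodes.tsv"))
  .writeTsv(study$siteAnnotations, p("sites.tsv"))
  .writeTsv(study$tfTargets, p("tf_targets.tsv"))
  writeInhibitorMap(study$inhibitorMap, p("inhibitor_map.tsv"))
  .writeTsv(study$cohort$binderTable, p("binders.tsv"))
  .writeTsv(data.frame(peptide = names(study$cohort$cohortPresence),
                       n_samples = unname(study$cohort$cohortPresence)),
            p("cohort.tsv"))
  .writeTsv(data.frame(peptide = names(study$cohort$benignPresence),
                       n_samples = unname(study$cohort$benignPresence)),
            p("benign.tsv"))
  writeLines(study$cohort$ctaProteins, p("cta.txt"))
  .writeTsv(study$annotations, p("annotations.tsv"))
  jsonlite::write_json(study$truth, p("ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")
  paths <- c(vapply(names(study$layers), function(nm)
    p(paste0(nm, ".tsv")), ""),
    network_edges = p("network_edges.tsv"),
    network_nodes = p("network_nodes.tsv"), sites = p("sites.tsv"),
    tf_targets = p("tf_targets.tsv"),
    inhibitor_map = p("inhibitor_map.tsv"), binders = p("binders.tsv"),
    cohort = p("cohort.tsv"), benign = p("benign.tsv"), cta = p("cta.txt"),
    annotations = p("annotations.tsv"),
    ground_truth = p("ground_truth.json"))
  invisible(paths)
}
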