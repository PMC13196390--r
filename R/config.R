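#' Analysis configuration
#'
#' Thresholds and caps for the preprocessing, differential, proximity and
#' mechanism stages. All values have the defaults used throughout the
#' package; unknown arguments are an error.
#'
#' @param fcThreshold absolute log2 fold-change threshold for significance
#'   (default 0.5).
#' @param fdrThreshold BH-adjusted p-value threshold (default 0.05).
#' @param detectionMin minimum number of replicates a feature must be
#'   detected in, within at least one condition (default 2, i.e. 2-of-3).
#' @param imputationQ quantile defining the left-censored imputation mean
#'   (default 0.01).
#' @param imputationSdScale imputation sd as a fraction of the per-sample
#'   observed sd (default 0.3).
#' @param m1MaxSteps,m2MaxSteps,m3MaxSteps step caps for the causal paths of
#'   mechanisms 1-3 (defaults 2, 2, 3).
#' @param proximityMaxPathLen path-length cap for the proximity screen
#'   (default 4).
#' @param consistencyMode `"lenient"` (peptide sign only) or `"strict"`
#'   (every measured supporting layer must match).
#' @param varEqual use the equal-variance Student t-test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @param strongBindersOnly restrict the antigen binder set to strong
#'   binders (default `FALSE`: strong and weak).
#' @param rngSeed integer seed for the stochastic stages.
#' @return a classed list (`AnalysisConfig`).
#' @export
analysisConfig <- function(fcThreshold = 0.5, fdrThreshold = 0.05,
                           detectionMin = 2L, imputationQ = 0.01,
                           imputationSdScale = 0.3,
                           m1MaxSteps = 2L, m2MaxSteps = 2L, m3MaxSteps = 3L,
                           proximityMaxPathLen = 4L,
                           consistencyMode = c("lenient", "strict"),
                           varEqual = TRUE, strongBindersOnly = FALSE,
                           rngSeed = 1L) {
  consistencyMode <- match.arg(consistencyMode)
  cfg <- list(fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
              detectionMin = as.integer(detectionMin),
              imputationQ = imputationQ,
              imputationSdScale = imputationSdScale,
              m1MaxSteps = as.integer(m1MaxSteps),
              m2MaxSteps = as.integer(m2MaxSteps),
              m3MaxSteps = as.integer(m3MaxSteps),
              proximityMaxPathLen = as.integer(proximityMaxPathLen),
              consistencyMode = consistencyMode, varEqual = varEqual,
              strongBindersOnly = strongBindersOnly,
              rngSeed = as.integer(rngSeed))
  stopifnot(cfg$fcThreshold > 0, cfg$fdrThreshold > 0,
            cfg$imputationQ > 0, cfg$imputationQ < 0.5,
            cfg$imputationSdScale > 0, cfg$detectionMin >= 1,
            cfg$m1MaxSteps >= 1, cfg$m2MaxSteps >= 1, cfg$m3MaxSteps >= 1,
            cfg$proximityMaxPathLen >= 1)
  structure(cfg, class = "AnalysisConfig")
}

#' Read an analysis configuration from a flat key = value file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Unknown keys are an error (this catches silent typos).
#'
#' @param path file path.
#' @return an `AnalysisConfig`.
#' @export
readAnalysisConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed config line (expected 'key = value'): ",
         lines[!grepl("=", lines, fixed = TRUE)][1])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- names(formals(analysisConfig))
  bad <- setdiff(keys, known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  for (k in keys) {
    if (k %in% c("consistencyMode")) next
    if (k %in% c("varEqual", "strongBindersOnly"))
      args[[k]] <- as.logical(args[[k]])
    else args[[k]] <- as.numeric(args[[k]])
  }
  do.call(analysisConfig, args)
}

#' Synthetic-study configuration
#'
#' Defines the simulated study: a four-condition (control plus three kinase
#' inhibitors), three-replicate design; log-normal baseline intensities;
#' planted treatment effects routed through the three mechanism motifs;
#' intensity-dependent (left-censored) missingness; and patient-cohort /
#' benign-tissue presence structure.
#'
#' @param nBackgroundNodes signaling nodes outside the planted motifs.
#' @param nMotifsPerMechanism planted motifs per mechanism per treatment.
#' @param nBackgroundPeptides background HLA-I peptides.
#' @param nBackgroundPhosphoPeptides background phosphorylated HLA-I
#'   peptides.
#' @param nBackgroundProteins background proteome features (also the pool of
#'   background peptide source proteins).
#' @param nBackgroundPhosphosites background phosphoproteome features.
#' @param targetsPerTF target genes per planted transcription factor (one
#'   presented peptide each).
#' @param nDecoyTFs drug-reachable TFs with targets but no planted effect.
#' @param baselineLog2Mean,baselineLog2Sd baseline log2-intensity
#'   distribution.
#' @param replicateNoiseSd replicate-level noise sd (log2 units).
#' @param plantedEffectLog2 magnitude of planted log2 fold-changes (sign is
#'   set by sign propagation through the motif).
#' @param missingPMax maximal missingness probability.
#' @param missingMidpoint intensity at half-maximal missingness; `NULL`
#'   means the 5th percentile of the simulated values.
#' @param missingSlope logistic slope of the missingness curve (log2 units).
#' @param cohortSize number of patient samples in the disease cohort.
#' @param benignSize number of benign-tissue samples.
#' @param nPlantedTAAs planted tumor-associated antigens (cohort-positive,
#'   benign-negative binders).
#' @param nCTAProteins cancer-testis antigen source proteins.
#' @param conditions,control condition labels; the non-control conditions
#'   are the three inhibitor treatments.
#' @param replicates replicates per condition.
#' @param rngSeed integer seed; every generator operation is deterministic
#'   under it.
#' @return a classed list (`SimulationConfig`).
#' @export
simulationConfig <- function(nBackgroundNodes = 100L,
                             nMotifsPerMechanism = 10L,
                             nBackgroundPeptides = 2000L,
                             nBackgroundPhosphoPeptides = 30L,
                             nBackgroundProteins = 500L,
                             nBackgroundPhosphosites = 800L,
                             targetsPerTF = 10L,
                             nDecoyTFs = 2L,
                             baselineLog2Mean = 25, baselineLog2Sd = 2,
                             replicateNoiseSd = 0.5,
                             plantedEffectLog2 = 2.0,
                             missingPMax = 0.3, missingMidpoint = NULL,
                             missingSlope = 1.0,
                             cohortSize = 21L, benignSize = 30L,
                             nPlantedTAAs = 30L, nCTAProteins = 15L,
                             conditions = c("control", "imatinib",
                                            "PP2", "SP600125"),
                             control = "control",
                             replicates = 3L, rngSeed = 1L) {
  cfg <- list(nBackgroundNodes = as.integer(nBackgroundNodes),
              nMotifsPerMechanism = as.integer(nMotifsPerMechanism),
              nBackgroundPeptides = as.integer(nBackgroundPeptides),
              nBackgroundPhosphoPeptides =
                as.integer(nBackgroundPhosphoPeptides),
              nBackgroundProteins = as.integer(nBackgroundProteins),
              nBackgroundPhosphosites = as.integer(nBackgroundPhosphosites),
              targetsPerTF = as.integer(targetsPerTF),
              nDecoyTFs = as.integer(nDecoyTFs),
              baselineLog2Mean = baselineLog2Mean,
              baselineLog2Sd = baselineLog2Sd,
              replicateNoiseSd = replicateNoiseSd,
              plantedEffectLog2 = plantedEffectLog2,
              missingPMax = missingPMax,
              missingMidpoint = missingMidpoint,
              missingSlope = missingSlope,
              cohortSize = as.integer(cohortSize),
              benignSize = as.integer(benignSize),
              nPlantedTAAs = as.integer(nPlantedTAAs),
              nCTAProteins = as.integer(nCTAProteins),
              conditions = conditions, control = control,
              replicates = as.integer(replicates),
              rngSeed = as.integer(rngSeed))
  stopifnot(cfg$nMotifsPerMechanism >= 1,
            cfg$nBackgroundPeptides >= 1, cfg$nBackgroundProteins >= 1,
            cfg$targetsPerTF >= 1,
            cfg$missingPMax >= 0, cfg$missingPMax <= 1,
            cfg$missingSlope > 0,
            cfg$replicateNoiseSd >= 0, cfg$plantedEffectLog2 > 0,
            cfg$cohortSize >= 1, cfg$benignSize >= 1,
            cfg$nPlantedTAAs >= 1,
            cfg$control %in% cfg$conditions,
            length(cfg$conditions) >= 2, cfg$replicates >= 2)
  structure(cfg, class = "SimulationConfig")
}

#' Derive a deterministic per-stage child seed
#'
#' Fans one run seed out into stable child seeds so pipeline stages can be
#' rerun in isolation; the result stays well below 2^31.
#'
#' @param seed integer run seed.
#' @param k stage index.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, k) {
  (as.integer(seed) %% 21474836L) * 97L + as.integer(k)
}

# evaluate `expr` under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

.pwLog <- function(...) {
  if (!isTRUE(getOption("pepwire.quiet", TRUE)))
    message("[pepwire] ", ...)
  invisible(NULL)
}
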