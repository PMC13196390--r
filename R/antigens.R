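#' Identify tumor-associated antigens
#'
#' A TAA is an MHC-I-binding peptide detected in at least one
#' disease-cohort sample and entirely absent from the benign-tissue
#' compartment. Peptide identity is the (case-normalized) amino-acid
#' string; a peptide missing from a presence map counts as absent.
#'
#' @param binderPeptides character vector of binder peptide sequences
#'   (strong and weak calls).
#' @param cohortPresence,benignPresence named integer vectors, peptide ->
#'   number of positive samples.
#' @return sorted character vector of TAA sequences.
#' @examples
#' identifyTAAs(c("P1", "P2", "P3", "P4"),
#'              c(P2 = 1L, P3 = 2L, P5 = 1L), c(P3 = 1L))  # "P2"
#' @export
identifyTAAs <- function(binderPeptides, cohortPresence, benignPresence) {
  binders <- unique(toupper(binderPeptides))
  names(cohortPresence) <- toupper(names(cohortPresence))
  names(benignPresence) <- toupper(names(benignPresence))
  coh <- cohortPresence[binders]; coh[is.na(coh)] <- 0L
  ben <- benignPresence[binders]; ben[is.na(ben)] <- 0L
  sort(binders[coh >= 1 & ben == 0])
}

#' Select putative TAAs: significantly upregulated under some inhibitor
#'
#' The subset of the TAA set whose presentation is significantly increased
#' (`significant` and `direction == "up"`) in at least one treatment.
#'
#' @param taaSet character vector of TAA peptide sequences.
#' @param pepResults [differentialTest()] output for the immunopeptidome.
#' @param annotations optional feature annotation data.frame mapping
#'   `feature_id` to `peptide_sequence`; when `NULL`, result feature ids
#'   are taken to be the sequences themselves.
#' @return sorted character vector of putative TAA sequences.
#' @export
selectPutativeTAAs <- function(taaSet, pepResults, annotations = NULL) {
  res <- pepResults
  seqs <- if (is.null(annotations)) toupper(res$feature_id)
          else toupper(annotations$peptide_sequence[
                 match(res$feature_id, annotations$feature_id)])
  up <- res$significant & res$direction == "up"
  sort(intersect(toupper(taaSet), unique(seqs[up & !is.na(seqs)])))
}

#' Cross-tabulate cancer-testis antigen derived peptides
#'
#' One row per presented peptide whose source protein is an annotated
#' cancer-testis antigen, with its cohort and benign sample counts;
#' deterministic (protein, peptide) row order.
#'
#' @param annotations feature annotation data.frame.
#' @param ctaProteins character vector of CTA protein ids.
#' @param cohortPresence,benignPresence named integer presence vectors.
#' @return a data.frame with columns `source_protein`, `peptide`,
#'   `n_cohort`, `n_benign`.
#' @export
ctaCrosstab <- function(annotations, ctaProteins, cohortPresence,
                        benignPresence) {
  pep <- annotations[annotations$feature_kind == "hla_peptide" &
                     annotations$source_protein %in% ctaProteins, ,
                     drop = FALSE]
  names(cohortPresence) <- toupper(names(cohortPresence))
  names(benignPresence) <- toupper(names(benignPresence))
  seqs <- toupper(pep$peptide_sequence)
  coh <- cohortPresence[seqs]; coh[is.na(coh)] <- 0L
  ben <- benignPresence[seqs]; ben[is.na(ben)] <- 0L
  out <- data.frame(source_protein = pep$source_protein, peptide = seqs,
                    n_cohort = unname(coh), n_benign = unname(ben),
                    stringsAsFactors = FALSE)
  out <- out[order(out$source_protein, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-format TAA modulation report
#'
#' For every TAA and every treatment: the differential statistics plus the
#' best binding allele and the predicted immunogenicity score, suitable for
#' volcano or heatmap plotting downstream. Rows number
#' `|taaSet| x nTreatments`.
#'
#' @param taaSet character vector of TAA peptide sequences.
#' @param pepResults [differentialTest()] output for the immunopeptidome.
#' @param annotations feature annotation data.frame (sequence and
#'   immunogenicity).
#' @param binderTable optional binder-call data.frame (`peptide`, `allele`,
#'   `binder_class`); the best allele prefers strong over weak over non
#'   calls.
#' @return a data.frame with columns `peptide`, `treatment`, `log2FC`,
#'   `adj_p_value`, `significant`, `direction`, `best_allele`,
#'   `immunogenicity_score`.
#' @export
taaModulationReport <- function(taaSet, pepResults, annotations,
                                binderTable = NULL) {
  taa <- sort(unique(toupper(taaSet)))
  trts <- sort(unique(pepResults$treatment))
  if (!length(taa) || !length(trts))
    return(data.frame(peptide = character(), treatment = character(),
                      log2FC = numeric(), adj_p_value = numeric(),
                      significant = logical(), direction = character(),
                      best_allele = character(),
                      immunogenicity_score = numeric(),
                      stringsAsFactors = FALSE))
  ann <- annotations[annotations$feature_kind == "hla_peptide", ,
                     drop = FALSE]
  fid <- ann$feature_id[match(taa, toupper(ann$peptide_sequence))]
  imm <- ann$immunogenicity_score[match(taa, toupper(ann$peptide_sequence))]
  best <- rep(NA_character_, length(taa))
  if (!is.null(binderTable)) {
    bt <- binderTable
    bt$rank <- match(bt$binder_class, c("strong", "weak", "non"))
    bt <- bt[order(bt$peptide, bt$rank, bt$allele), , drop = FALSE]
    bt <- bt[!duplicated(bt$peptide), , drop = FALSE]
    best <- bt$allele[match(taa, toupper(bt$peptide))]
  }
  grid <- expand.grid(idx = seq_along(taa), treatment = trts,
                      stringsAsFactors = FALSE)
  key <- paste(fid[grid$idx], grid$treatment, sep = "\r")
  rkey <- paste(pepResults$feature_id, pepResults$treatment, sep = "\r")
  hit <- match(key, rkey)
  out <- data.frame(peptide = taa[grid$idx], treatment = grid$treatment,
                    log2FC = pepResults$log2FC[hit],
                    adj_p_value = pepResults$adj_p_value[hit],
                    significant = pepResults$significant[hit],
                    direction = pepResults$direction[hit],
                    best_allele = best[grid$idx],
                    immunogenicity_score = imm[grid$idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$peptide, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binder peptide set from a binder-call table
#'
#' @param binderTable data.frame with `peptide` and `binder_class`.
#' @param strongOnly restrict to strong binders (default: strong + weak).
#' @return character vector of binder sequences.
#' @export
binderPeptides <- function(binderTable, strongOnly = FALSE) {
  keep <- if (strongOnly) binderTable$binder_class == "strong"
          else binderTable$binder_class %in% c("strong", "weak")
  unique(toupper(binderTable$peptide[keep]))
}
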