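#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

.readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

.writeTsv <- function(df, path) {
  # doubles serialized with 17 significant digits so write -> read is the
  # identity on every value
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.infinite(df[[j]])] <- ifelse(df[[j]][is.infinite(df[[j]])] > 0,
                                        "Inf", "-Inf")
      x[is.na(df[[j]])] <- NA_character_
      df[[j]] <- x
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a feature x sample intensity matrix
#'
#' Expects a TSV with a `feature_id` column followed by one column per
#' sample; an empty cell or the literal `NA` marks a missing measurement.
#' Columns are reordered to follow `design`; a header column absent from
#' the design, or a duplicated feature id, is a hard error naming the
#' offender.
#'
#' @param path TSV file path.
#' @param layer layer label (see [OmicsLayer-class]).
#' @param design a [SampleDesign-class].
#' @param scale intensity scale of the file, `"raw"` or `"log2"`.
#' @return an [OmicsLayer-class].
#' @export
readIntensityMatrix <- function(path, layer, design,
                                scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- .readTsv(path)
  if (names(df)[1] != "feature_id")
    stop("first column of ", path, " must be 'feature_id'")
  unknown <- setdiff(names(df)[-1], design@sampleIds)
  if (length(unknown))
    stop("sample column(s) not in design: ", paste(unknown, collapse = ", "))
  miss <- setdiff(design@sampleIds, names(df)[-1])
  if (length(miss))
    stop("design sample(s) absent from file: ", paste(miss, collapse = ", "))
  dup <- df$feature_id[duplicated(df$feature_id)]
  if (length(dup))
    stop("duplicated feature_id: ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, design@sampleIds, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  OmicsLayer(m, layer = layer, design = design, scale = scale)
}

#' Write an intensity matrix as TSV
#'
#' Inverse of [readIntensityMatrix()]; missing cells are written as `NA`.
#'
#' @param x an [OmicsLayer-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeIntensityMatrix <- function(x, path) {
  m <- intensities(x)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' Read a causal network from edge and node TSVs
#'
#' The edge list has columns `source`, `target`, `sign` (+1/-1),
#' `edge_type`, `site_residue`, `site_position`; the node table has `id`
#' plus attribute columns. A sign outside {+1, -1} or an edge endpoint
#' missing from the node table is a validation error.
#'
#' @param edgePath,nodePath TSV paths.
#' @return a [CausalNetwork-class].
#' @export
readCausalNetwork <- function(edgePath, nodePath) {
  ed <- .readTsv(edgePath)
  nd <- .readTsv(nodePath)
  if (nrow(ed) && !all(ed$sign %in% c(-1, 1)))
    stop("edge sign outside {+1,-1} in ", edgePath, ": row ",
         which(!ed$sign %in% c(-1, 1))[1])
  for (col in c("is_kinase", "is_tf", "is_druggable", "in_target_pathway"))
    if (col %in% names(nd)) nd[[col]] <- as.logical(nd[[col]])
  if ("family_members" %in% names(nd)) {
    nd$family_members <- as.character(nd$family_members)
    nd$family_members[is.na(nd$family_members)] <- ""
  }
  if ("site_residue" %in% names(ed))
    ed$site_residue <- as.character(ed$site_residue)
  if ("site_position" %in% names(ed))
    ed$site_position <- as.integer(ed$site_position)
  net <- CausalNetwork(nodes = nd, edges = ed)
  validObject(net)
  net
}

#' Write a causal network to edge and node TSVs
#'
#' @param net a [CausalNetwork-class].
#' @param edgePath,nodePath output paths.
#' @return invisibly, the two paths.
#' @export
writeCausalNetwork <- function(net, edgePath, nodePath) {
  .writeTsv(networkEdges(net), edgePath)
  .writeTsv(networkNodes(net), nodePath)
  invisible(c(edgePath, nodePath))
}

#' Read phosphosite functional annotations
#'
#' TSV with columns `protein_id`, `residue`, `position` (1-based),
#' `functional_effect` (one of `activates_protein`, `inhibits_protein`,
#' `stabilizes_protein`, `destabilizes_protein`) and `upstream_kinases`
#' (comma-separated node ids).
#'
#' @param path TSV path.
#' @return a data.frame of site annotations.
#' @export
readSiteAnnotations <- function(path) {
  df <- .readTsv(path)
  bad <- setdiff(df$functional_effect, .SITE_EFFECTS)
  if (length(bad))
    stop("unknown functional_effect: ", paste(bad, collapse = ", "))
  key <- paste(df$protein_id, df$residue, df$position)
  if (anyDuplicated(key))
    stop("duplicated (protein, residue, position): ", key[duplicated(key)][1])
  df$upstream_kinases[is.na(df$upstream_kinases)] <- ""
  df
}

#' Read a TF-target table
#'
#' TSV with columns `tf_id`, `target_id`, `regulation_sign` (+1/-1).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
readTFTargets <- function(path) {
  df <- .readTsv(path)
  if (nrow(df) && !all(df$regulation_sign %in% c(-1, 1)))
    stop("regulation_sign outside {+1,-1} in ", path)
  if (anyDuplicated(paste(df$tf_id, df$target_id)))
    stop("duplicated (tf, target) pair in ", path)
  df
}

#' Read an inhibitor map
#'
#' TSV with columns `treatment` and `inhibited_kinases` (comma-separated
#' node ids); returns a named list treatment -> character vector.
#'
#' @param path TSV path.
#' @return a named list.
#' @export
readInhibitorMap <- function(path) {
  df <- .readTsv(path)
  setNames(strsplit(df$inhibited_kinases, ","), df$treatment)
}

#' Write an inhibitor map
#' @param map named list treatment -> inhibited kinase ids.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeInhibitorMap <- function(map, path) {
  .writeTsv(data.frame(treatment = names(map),
                       inhibited_kinases = vapply(map, paste,
                                                  "", collapse = ","),
                       stringsAsFactors = FALSE), path)
}

#' Read peptide presence counts
#'
#' TSV with columns `peptide` (amino-acid sequence) and `n_samples`;
#' returns a named integer vector. Sequences are upper-cased.
#'
#' @param path TSV path.
#' @return named integer vector, peptide -> number of positive samples.
#' @export
readPresenceCounts <- function(path) {
  df <- .readTsv(path)
  setNames(as.integer(df$n_samples), toupper(df$peptide))
}

#' Read a one-peptide-per-line list
#' @param path text file path.
#' @return upper-cased character vector.
#' @export
readPeptideList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  toupper(x[nzchar(x)])
}

#' Read a binder-call table
#'
#' TSV with columns `peptide`, `allele`, `binder_class`
#' (strong/weak/non).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
readBinderTable <- function(path) {
  df <- .readTsv(path)
  bad <- setdiff(df$binder_class, c("strong", "weak", "non"))
  if (length(bad))
    stop("unknown binder_class: ", paste(bad, collapse = ", "))
  df$peptide <- toupper(df$peptide)
  df
}

#' Write a results bundle with a JSON manifest
#'
#' Writes one TSV per named element of `results` plus `manifest.json`
#' echoing the configuration and seed and recording per-table row counts
#' and md5 digests. Byte-stable for identical inputs.
#'
#' @param results named list of data.frames.
#' @param outDir output directory (created if absent).
#' @param config an `AnalysisConfig` (echoed into the manifest), or `NULL`.
#' @param seed the run seed, or `NULL`.
#' @return the manifest, invisibly.
#' @export
writeResultsBundle <- function(results, outDir, config = NULL, seed = NULL) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  counts <- list(); digests <- list()
  for (nm in names(results)) {
    path <- file.path(outDir, paste0(nm, ".tsv"))
    df <- as.data.frame(results[[nm]])
    .writeTsv(df, path)
    counts[[nm]] <- nrow(df)
    digests[[nm]] <- unname(tools::md5sum(path))
  }
  manifest <- list(config = unclass(config), seed = seed,
                   tables = names(results), row_counts = counts,
                   digests = digests)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
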