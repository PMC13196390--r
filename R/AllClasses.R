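#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

.LAYERS <- c("immunopeptidome", "phospho_immunopeptidome",
             "proteome", "phosphoproteome")
.EDGE_TYPES <- c("phosphorylation", "transcriptional", "stability", "other")
.SITE_EFFECTS <- c("activates_protein", "inhibits_protein",
                   "stabilizes_protein", "destabilizes_protein")

#' Experimental design of a treatment-versus-control omics experiment
#'
#' Holds the condition labels (one designated control), the per-condition
#' replicate count and the derived sample identifiers. Every sample id maps
#' to exactly one (condition, replicate) pair.
#'
#' @slot conditions ordered character vector of condition labels.
#' @slot control the single control condition label.
#' @slot replicates integer, replicates per condition (>= 2).
#' @slot sampleIds character vector, one id per sample.
#' @slot condition character vector, condition of each sample.
#' @slot replicate integer vector, replicate index of each sample.
#' @export
setClass("SampleDesign",
  slots = c(conditions = "character", control = "character",
            replicates = "integer", sampleIds = "character",
            condition = "character", replicate = "integer"))

setValidity("SampleDesign", function(object) {
  msg <- character()
  if (length(object@control) != 1L ||
      sum(object@conditions == object@control) != 1L)
    msg <- c(msg, "exactly one control condition is required")
  if (anyDuplicated(object@conditions))
    msg <- c(msg, "duplicated condition labels")
  if (object@replicates < 2L)
    msg <- c(msg, "at least 2 replicates per condition are required")
  n <- length(object@conditions) * object@replicates
  if (length(object@sampleIds) != n ||
      length(object@condition) != n || length(object@replicate) != n)
    msg <- c(msg, "sample bookkeeping does not match conditions x replicates")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicated sample ids")
  if (!all(object@condition %in% object@conditions))
    msg <- c(msg, "sample condition outside the declared conditions")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleDesign
#'
#' @param conditions character vector of condition labels.
#' @param control control condition label (default: first condition).
#' @param replicates replicates per condition (default 3, as in a
#'   biological-triplicate design).
#' @return a [SampleDesign-class] object; sample ids are
#'   `<condition>_r<replicate>`.
#' @examples
#' SampleDesign(c("control", "imatinib"), replicates = 3)
#' @export
SampleDesign <- function(conditions, control = conditions[1], replicates = 3L) {
  replicates <- as.integer(replicates)
  cond <- rep(conditions, each = replicates)
  repl <- rep(seq_len(replicates), times = length(conditions))
  new("SampleDesign", conditions = conditions, control = control,
      replicates = replicates,
      sampleIds = paste0(cond, "_r", repl),
      condition = cond, replicate = repl)
}

#' Single-layer intensity matrix with explicit missingness
#'
#' A \linkS4class{SummarizedExperiment} carrying one `intensity` assay
#' (features x samples; `NA` marks a missing measurement), the layer label
#' and the intensity scale. After log2 transformation every present value
#' must be finite.
#'
#' @slot layer one of `immunopeptidome`, `phospho_immunopeptidome`,
#'   `proteome`, `phosphoproteome`.
#' @slot scaleFlag `"raw"` or `"log2"`.
#' @slot design the [SampleDesign-class] of the experiment.
#' @export
setClass("OmicsLayer", contains = "SummarizedExperiment",
  slots = c(layer = "character", scaleFlag = "character",
            design = "SampleDesign"))

setValidity("OmicsLayer", function(object) {
  msg <- character()
  if (!object@layer %in% .LAYERS)
    msg <- c(msg, paste0("unknown layer '", object@layer, "'"))
  if (!object@scaleFlag %in% c("raw", "log2"))
    msg <- c(msg, "scaleFlag must be 'raw' or 'log2'")
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "an 'intensity' assay is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated feature ids")
  if (!identical(colnames(object), object@design@sampleIds))
    msg <- c(msg, "column names do not match the design sample ids")
  if (object@scaleFlag == "log2" && "intensity" %in% names(assays(object))) {
    v <- assay(object, "intensity")
    if (any(!is.finite(v[!is.na(v)])))
      msg <- c(msg, "non-finite log2 intensities")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsLayer
#'
#' @param values numeric matrix, features x samples; `NA` = missing.
#'   Column order must follow `design`.
#' @param layer layer label, see [OmicsLayer-class].
#' @param design a [SampleDesign-class].
#' @param scale `"raw"` or `"log2"`.
#' @return an [OmicsLayer-class].
#' @export
OmicsLayer <- function(values, layer, design, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (is.null(colnames(values))) colnames(values) <- design@sampleIds
  cd <- DataFrame(condition = design@condition,
                  replicate = design@replicate,
                  row.names = design@sampleIds)
  se <- SummarizedExperiment(assays = list(intensity = values), colData = cd)
  new("OmicsLayer", se, layer = layer, scaleFlag = scale, design = design)
}

#' Signed, typed, directed causal interaction network
#'
#' Nodes carry kinase/TF/druggability flags, optional family membership and
#' an optional target-pathway membership flag (used by the proximity
#' screen). Edges are signed (+1 activation / up-regulation, -1 inhibition
#' / down-regulation), typed, and may carry a residue-level phosphosite on
#' the target.
#'
#' @slot nodes data.frame with columns `id`, `is_kinase`, `is_tf`,
#'   `is_druggable`, `family_members` (comma-separated ids or `""`),
#'   `in_target_pathway`.
#' @slot edges data.frame with columns `source`, `target`, `sign`,
#'   `edge_type`, `site_residue`, `site_position`.
#' @export
setClass("CausalNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame"))

setValidity("CausalNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  msg <- character()
  need_n <- c("id", "is_kinase", "is_tf", "is_druggable",
              "family_members", "in_target_pathway")
  need_e <- c("source", "target", "sign", "edge_type",
              "site_residue", "site_position")
  if (!all(need_n %in% names(nd)))
    return(paste("node table lacks columns:",
                 paste(setdiff(need_n, names(nd)), collapse = ", ")))
  if (!all(need_e %in% names(ed)))
    return(paste("edge table lacks columns:",
                 paste(setdiff(need_e, names(ed)), collapse = ", ")))
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicated node ids")
  dangling <- setdiff(c(ed$source, ed$target), nd$id)
  if (length(dangling))
    msg <- c(msg, paste("dangling edge endpoints:",
                        paste(utils::head(dangling, 5), collapse = ", ")))
  if (nrow(ed) && !all(ed$sign %in% c(-1L, 1L)))
    msg <- c(msg, "edge signs must be +1 or -1")
  if (nrow(ed) && !all(ed$edge_type %in% .EDGE_TYPES))
    msg <- c(msg, "unknown edge_type")
  if (nrow(ed)) {
    tf_src <- nd$id[nd$is_tf]
    bad <- ed$edge_type == "transcriptional" & !(ed$source %in% tf_src)
    if (any(bad))
      msg <- c(msg, "transcriptional edges must originate from TF nodes")
    kin_src <- nd$id[nd$is_kinase]
    badk <- ed$edge_type == "phosphorylation" & !(ed$source %in% kin_src)
    if (any(badk))
      msg <- c(msg, "phosphorylation edges must originate from kinase nodes")
    selfp <- ed$edge_type == "phosphorylation" & ed$source == ed$target &
      (is.na(ed$site_residue) | ed$site_residue == "")
    if (any(selfp))
      msg <- c(msg, "self phosphorylation edges require a residue")
  }
  fam <- unlist(strsplit(nd$family_members[nd$family_members != ""], ","))
  if (length(fam) && !all(fam %in% nd$id))
    msg <- c(msg, "family_members reference unknown nodes")
  if (length(msg)) msg else TRUE
})

#' Construct a CausalNetwork
#'
#' @param nodes node attribute data.frame (missing attribute columns are
#'   filled with defaults).
#' @param edges edge list data.frame with at least `source`, `target`,
#'   `sign`; `edge_type` defaults to `"other"`.
#' @return a [CausalNetwork-class].
#' @examples
#' CausalNetwork(
#'   nodes = data.frame(id = c("A", "B"), is_kinase = TRUE),
#'   edges = data.frame(source = "A", target = "B", sign = -1L))
#' @export
CausalNetwork <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"is_kinase" %in% names(nodes)) nodes$is_kinase <- FALSE
  if (!"is_tf" %in% names(nodes)) nodes$is_tf <- FALSE
  if (!"is_druggable" %in% names(nodes)) nodes$is_druggable <- FALSE
  if (!"family_members" %in% names(nodes)) nodes$family_members <- ""
  if (!"in_target_pathway" %in% names(nodes)) nodes$in_target_pathway <- FALSE
  nodes$family_members[is.na(nodes$family_members)] <- ""
  if (!"edge_type" %in% names(edges))
    edges$edge_type <- rep("other", nrow(edges))
  if (!"site_residue" %in% names(edges))
    edges$site_residue <- rep(NA_character_, nrow(edges))
  if (!"site_position" %in% names(edges))
    edges$site_position <- rep(NA_integer_, nrow(edges))
  if (nrow(edges)) edges$sign <- as.integer(edges$sign)
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("CausalNetwork", nodes = nodes, edges = edges)
}
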