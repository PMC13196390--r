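#' @describeIn OmicsLayer-class the intensity assay matrix.
#' @export
setMethod("intensities", "OmicsLayer", function(x) assay(x, "intensity"))

#' @describeIn OmicsLayer-class the layer label.
#' @export
setMethod("layerType", "OmicsLayer", function(x) x@layer)

#' @describeIn OmicsLayer-class `"raw"` or `"log2"`.
#' @export
setMethod("intensityScale", "OmicsLayer", function(x) x@scaleFlag)

#' @describeIn OmicsLayer-class the experimental design.
#' @export
setMethod("sampleDesign", "OmicsLayer", function(x) x@design)

#' @describeIn SampleDesign-class the control condition label.
#' @export
setMethod("controlCondition", "SampleDesign", function(x) x@control)

#' @describeIn SampleDesign-class the non-control condition labels.
#' @export
setMethod("treatments", "SampleDesign",
          function(x) setdiff(x@conditions, x@control))

#' @describeIn CausalNetwork-class the node attribute table.
#' @export
setMethod("networkNodes", "CausalNetwork", function(x) x@nodes)

#' @describeIn CausalNetwork-class the edge list.
#' @export
setMethod("networkEdges", "CausalNetwork", function(x) x@edges)

setMethod("show", "SampleDesign", function(object) {
  cat("SampleDesign:", length(object@conditions), "conditions x",
      object@replicates, "replicates\n")
  cat("  control:", object@control, "\n")
  cat("  treatments:", paste(treatments(object), collapse = ", "), "\n")
})

setMethod("show", "OmicsLayer", function(object) {
  v <- assay(object, "intensity")
  cat("OmicsLayer '", object@layer, "' (", object@scaleFlag, " scale): ",
      nrow(v), " features x ", ncol(v), " samples, ",
      sum(is.na(v)), " missing cells\n", sep = "")
  callNextMethod()
})

setMethod("show", "CausalNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  cat("CausalNetwork:", nrow(nd), "nodes,", nrow(ed), "edges\n")
  cat("  kinases:", sum(nd$is_kinase), " TFs:", sum(nd$is_tf),
      " druggable:", sum(nd$is_druggable),
      " target-pathway members:", sum(nd$in_target_pathway), "\n")
  if (nrow(ed))
    cat("  edge types:",
        paste(names(table(ed$edge_type)), table(ed$edge_type),
              sep = "=", collapse = ", "), "\n")
})

# directed igraph view of a CausalNetwork (internal)
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    net@edges[, c("source", "target"), drop = FALSE],
    directed = TRUE, vertices = net@nodes$id)
}

# expand a node id to itself plus any family members (internal)
.expandFamily <- function(net, ids) {
  nd <- net@nodes
  fam <- nd$family_members[match(ids, nd$id)]
  fam <- fam[!is.na(fam) & fam != ""]
  unique(c(ids, unlist(strsplit(fam, ","))))
}
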