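#' @rdname OmicsLayer-class
#' @param x an object.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname OmicsLayer-class
#' @export
setGeneric("layerType", function(x) standardGeneric("layerType"))

#' @rdname OmicsLayer-class
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' @rdname OmicsLayer-class
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' @rdname SampleDesign-class
#' @param x an object.
#' @export
setGeneric("controlCondition", function(x) standardGeneric("controlCondition"))

#' @rdname SampleDesign-class
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))

#' @rdname CausalNetwork-class
#' @param x an object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CausalNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
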