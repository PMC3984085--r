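#' @rdname geneNames
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname sampleNames
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname nGenes
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname nSamples
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname vertexNames
#' @export
setGeneric("vertexNames", function(x) standardGeneric("vertexNames"))

#' @rdname edgeMatrix
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname edgeCount
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname parentSets
#' @export
setGeneric("parentSets", function(x) standardGeneric("parentSets"))

#' @rdname skeleton
#' @export
setGeneric("skeleton", function(x) standardGeneric("skeleton"))

#' @rdname levelMatrix
#' @export
setGeneric("levelMatrix", function(x) standardGeneric("levelMatrix"))

#' @rdname levelCardinality
#' @export
setGeneric("levelCardinality", function(x) standardGeneric("levelCardinality"))
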