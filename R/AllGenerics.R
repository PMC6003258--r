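#' @import methods
#' @importFrom BiocGenerics sizeFactors counts
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' @rdname fpkm
#' @export
setGeneric("fpkm", function(object, ...) standardGeneric("fpkm"))

#' @rdname trioLine
#' @export
setGeneric("trioLine", function(object) standardGeneric("trioLine"))

#' @rdname trioLine
#' @export
setGeneric("trioReplicate", function(object) standardGeneric("trioReplicate"))

#' @rdname geneLengths
#' @export
setGeneric("geneLengths", function(object) standardGeneric("geneLengths"))

#' @rdname geneLengths
#' @export
setGeneric("geneLengths<-",
           function(object, value) standardGeneric("geneLengths<-"))

#' @rdname replicateR2
#' @export
setGeneric("replicateR2", function(object, ...) standardGeneric("replicateR2"))

#' @rdname nbDifferentialExpression
#' @export
setGeneric("nbDifferentialExpression",
           function(object, ...) standardGeneric("nbDifferentialExpression"))

#' @rdname inheritanceModes
#' @export
setGeneric("inheritanceModes",
           function(object, ...) standardGeneric("inheritanceModes"))
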