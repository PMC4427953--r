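#' @rdname ComplexSet-class
#' @param x,object a \code{ComplexSet}
#' @export
setGeneric("complexIds", function(x) standardGeneric("complexIds"))

#' @rdname ComplexSet-class
#' @export
setGeneric("members", function(x, ...) standardGeneric("members"))

#' @rdname ComplexSet-class
#' @export
setGeneric("complexNames", function(x) standardGeneric("complexNames"))

#' @rdname WeightedNetwork-class
#' @param x,object a \code{WeightedNetwork}
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname adjacencyMatrix
#' @export
setGeneric("adjacencyMatrix", function(x, ...)
  standardGeneric("adjacencyMatrix"))

#' @rdname ScoreVector-class
#' @param x,object a \code{ScoreVector}
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname RocResult-class
#' @param x,object a \code{RocResult}
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname RocResult-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname GoDag-class
#' @param x,object a \code{GoDag}
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))

#' @rdname GoDag-class
#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))
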