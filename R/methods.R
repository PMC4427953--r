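# Accessors and show methods for the core classes.

#' @rdname ComplexSet-class
#' @export
setMethod("complexIds", "ComplexSet", function(x) names(x@members))

#' @rdname ComplexSet-class
#' @param ids optional character vector restricting which complexes to return
#' @param ... unused
#' @export
setMethod("members", "ComplexSet", function(x, ids = NULL, ...) {
  if (is.null(ids)) return(x@members)
  missing <- setdiff(ids, names(x@members))
  if (length(missing))
    stop("unknown complex id(s): ", paste(missing, collapse = ", "))
  x@members[ids]
})

#' @rdname ComplexSet-class
#' @export
setMethod("complexNames", "ComplexSet", function(x) x@complexNames)

#' @rdname ComplexSet-class
#' @export
setMethod("length", "ComplexSet", function(x) length(x@members))

#' @rdname ComplexSet-class
#' @param i character or integer index of complexes to keep
#' @param j,drop ignored
#' @export
setMethod("[", "ComplexSet", function(x, i, j, ..., drop = FALSE) {
  ComplexSet(x@members[i], x@complexNames[i])
})

setMethod("show", "ComplexSet", function(object) {
  sizes <- lengths(object@members)
  cat(sprintf("ComplexSet with %d complexes over %d genes\n",
              length(object@members),
              length(unique(unlist(object@members, use.names = FALSE)))))
  if (length(sizes))
    cat(sprintf("  complex sizes: min %d / median %g / max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
})

#' @rdname WeightedNetwork-class
#' @export
setMethod("nodes", "WeightedNetwork", function(x) x@nodes)

#' @rdname WeightedNetwork-class
#' @export
setMethod("edges", "WeightedNetwork", function(x) x@edges)

#' @rdname WeightedNetwork-class
#' @export
setMethod("numNodes", "WeightedNetwork", function(x) length(x@nodes))

#' @rdname WeightedNetwork-class
#' @export
setMethod("numEdges", "WeightedNetwork", function(x) nrow(x@edges))

setMethod("show", "WeightedNetwork", function(object) {
  st <- networkStats(object)
  cat(sprintf(
    "WeightedNetwork: %d nodes, %d edges, density %.4g\n",
    st$nodes, st$edges, st$density))
  if (nrow(object@edges))
    cat(sprintf("  weights in [%.4g, %.4g]\n",
                min(object@edges$weight), max(object@edges$weight)))
})

#' Symmetric sparse adjacency matrix of a network
#'
#' @param x a [WeightedNetwork-class]
#' @param nodes optional node universe for the matrix dimensions (defaults
#'   to \code{nodes(x)}); extra nodes get zero rows/columns.
#' @param ... unused
#' @return a symmetric \code{dgCMatrix} with dimnames set to the node ids.
#' @export
setMethod("adjacencyMatrix", "WeightedNetwork", function(x, nodes = NULL,
                                                         ...) {
  if (is.null(nodes)) nodes <- x@nodes
  e <- x@edges
  keep <- e$from %in% nodes & e$to %in% nodes
  e <- e[keep, , drop = FALSE]
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  A <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = c(e$weight, e$weight),
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes))
  methods::as(A, "CsparseMatrix")
})

#' @rdname ScoreVector-class
#' @export
setMethod("scores", "ScoreVector", function(x) x@scores)

setMethod("show", "ScoreVector", function(object) {
  par <- if (length(object@parameters))
    paste0(" (", paste(names(object@parameters), unlist(object@parameters),
                       sep = "=", collapse = ", "), ")") else ""
  cat(sprintf("ScoreVector: %s%s over %d nodes, %d iterations\n",
              object@algorithm, par, length(object@scores),
              object@iterations))
})

#' @rdname RocResult-class
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

#' ROC curve points
#'
#' @param x a [RocResult-class]
#' @return data.frame with columns \code{tau}, \code{sensitivity} (pooled
#'   TP/(TP+FN)) and \code{fpr} (pooled FP/(FP+TN)); includes the (0, 0)
#'   origin at \code{tau = 0}.
#' @rdname RocResult-class
#' @export
setMethod("rocPoints", "RocResult", function(x) {
  data.frame(
    tau = c(0, x@tau),
    sensitivity = c(0, x@tp / x@nPos),
    fpr = c(0, x@fp / x@nNeg))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC %.5f over %d held-out folds (%d thresholds)\n",
              object@auc, length(object@heldOutRanks), length(object@tau)))
})

#' @rdname GoDag-class
#' @export
setMethod("goTerms", "GoDag", function(x) x@terms)

#' @rdname GoDag-class
#' @export
setMethod("goRoots", "GoDag", function(x) x@roots)

setMethod("show", "GoDag", function(object) {
  cat(sprintf("GoDag: %d terms, %d parent edges, roots: %s\n",
              length(object@terms),
              sum(lengths(object@parents)),
              paste(names(object@roots), object@roots, sep = "=",
                    collapse = ", ")))
})
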