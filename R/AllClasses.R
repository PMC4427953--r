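#' @import methods
NULL

#' Set of protein complexes
#'
#' A \code{ComplexSet} holds protein complexes keyed by an opaque complex
#' identifier. Each complex is a non-empty set of gene identifiers (its
#' subunits). Gene identifiers are treated as opaque, case-sensitive strings:
#' no symbol/Entrez mapping is attempted.
#'
#' @slot members named list; one character vector of unique gene identifiers
#'   per complex, names are the complex ids.
#' @slot complexNames named character; free-text complex names, parallel to
#'   \code{members}.
#'
#' @seealso [readComplexes()], [buildNetwork()]
#' @export
setClass("ComplexSet",
  representation(members = "list", complexNames = "character"))

setValidity("ComplexSet", function(object) {
  ids <- names(object@members)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("all complexes must have non-empty ids")
  if (anyDuplicated(ids))
    return("duplicate complex ids")
  if (!identical(names(object@complexNames), ids))
    return("complexNames must be parallel to members")
  for (i in seq_along(object@members)) {
    m <- object@members[[i]]
    if (!is.character(m) || length(m) == 0L)
      return(sprintf("complex '%s' has an empty member set", ids[i]))
    if (anyDuplicated(m))
      return(sprintf("complex '%s' has duplicate members", ids[i]))
  }
  TRUE
})

#' Construct a ComplexSet
#'
#' @param members named list of character vectors (gene identifiers per
#'   complex); duplicated members within a complex are removed.
#' @param complexNames optional character vector of display names, recycled
#'   from the ids when missing.
#' @return A [ComplexSet-class] object.
#' @examples
#' cs <- ComplexSet(list(c1 = c("A", "B"), c2 = c("B", "C", "D")))
#' complexIds(cs)
#' @export
ComplexSet <- function(members, complexNames = NULL) {
  members <- lapply(members, function(m) unique(as.character(m)))
  if (is.null(complexNames)) complexNames <- names(members)
  complexNames <- as.character(complexNames)
  names(complexNames) <- names(members)
  new("ComplexSet", members = members, complexNames = complexNames)
}

#' Undirected weighted network over protein complexes
#'
#' Edge-list representation of an undirected weighted graph. Each unordered
#' pair is stored once with \code{from < to} (lexicographic); weights are
#' strictly positive and, for all similarity modes implemented here, bounded
#' by 1. Nodes may be listed without incident edges only when a network is
#' built with \code{keepIsolated = TRUE}.
#'
#' @slot nodes character vector of node (complex) ids.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#'
#' @seealso [buildNetwork()], [adjacencyMatrix()], [networkStats()]
#' @export
setClass("WeightedNetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("WeightedNetwork", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% colnames(e)))
    return("edges must have columns from, to, weight")
  if (anyDuplicated(object@nodes))
    return("duplicate node ids")
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$from > e$to)) return("edges must be stored with from < to")
    if (anyDuplicated(paste0(e$from, "\r", e$to)))
      return("duplicate edges")
    if (!all(c(e$from, e$to) %in% object@nodes))
      return("edge endpoints missing from node set")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      return("edge weights must be finite and > 0")
  }
  TRUE
})

#' Construct a WeightedNetwork
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}; pairs are canonicalised (smaller id first) and may be
#'   supplied in either orientation.
#' @param nodes optional character vector of node ids; defaults to the ids
#'   occurring in \code{edges}.
#' @return A [WeightedNetwork-class] object.
#' @export
WeightedNetwork <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    edges <- data.frame(from = from, to = to,
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    o <- order(edges$from, edges$to)
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  new("WeightedNetwork", nodes = as.character(nodes), edges = edges)
}

#' Gene Ontology DAG
#'
#' Directed acyclic graph over GO term ids with edges pointing from a child
#' term to its parents (following \code{is_a} and \code{part_of}). The three
#' canonical sub-ontology roots are GO:0008150 (biological process,
#' BP), GO:0005575 (cellular component, CC) and GO:0003674 (molecular
#' function, MF); ancestor closures never include them.
#'
#' @slot terms character vector of term ids.
#' @slot parents named list mapping each term id to the character vector of
#'   its direct parents (empty for roots).
#' @slot roots named character of length <= 3 with names in BP/CC/MF.
#' @slot namespace named character mapping term id to its sub-ontology tag.
#'
#' @seealso [readObo()], [goAncestors()], [complexGoProfile()]
#' @export
setClass("GoDag",
  representation(terms = "character", parents = "list",
                 roots = "character", namespace = "character"))

setValidity("GoDag", function(object) {
  if (anyDuplicated(object@terms)) return("duplicate term ids")
  if (!identical(sort(names(object@parents)), sort(object@terms)))
    return("parents must be keyed by exactly the term ids")
  bad <- setdiff(unlist(object@parents, use.names = FALSE), object@terms)
  if (length(bad))
    return(sprintf("parent term(s) not in DAG: %s",
                   paste(utils::head(bad, 3), collapse = ", ")))
  if (length(object@roots) &&
      !all(names(object@roots) %in% c("BP", "CC", "MF")))
    return("root names must be BP, CC or MF")
  TRUE
})

#' Construct a GoDag
#'
#' @param parents named list: term id -> character vector of direct parents.
#' @param roots named character: sub-ontology tag (BP/CC/MF) -> root term id.
#' @param namespace optional named character: term id -> sub-ontology tag.
#' @return A [GoDag-class] object.
#' @export
GoDag <- function(parents, roots, namespace = character()) {
  terms <- names(parents)
  dag <- new("GoDag", terms = terms,
             parents = lapply(parents, as.character),
             roots = roots, namespace = namespace)
  if (.dagHasCycle(dag)) stop("GO graph contains a cycle")
  dag
}

# Kahn's algorithm on child->parent edges; TRUE if some node never clears.
.dagHasCycle <- function(dag) {
  indeg <- vapply(dag@parents, length, integer(1))  # number of parents left
  children <- split(
    rep(names(dag@parents), lengths(dag@parents)),
    unlist(dag@parents, use.names = FALSE))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen < length(dag@terms)
}

#' Node scores from one ranking algorithm
#'
#' @slot scores named numeric; one score per network node.
#' @slot algorithm character; one of \code{"nbh"}, \code{"rwr"},
#'   \code{"prince"}.
#' @slot parameters list; \code{gamma} for RWR, \code{alpha} for PRINCE,
#'   empty for NBH.
#' @slot iterations integer; number of propagation iterations (0 for NBH).
#'
#' @seealso [nbhScore()], [rwrScore()], [princeScore()], [rankScores()]
#' @export
setClass("ScoreVector",
  representation(scores = "numeric", algorithm = "character",
                 parameters = "list", iterations = "integer"))

setValidity("ScoreVector", function(object) {
  if (is.null(names(object@scores))) return("scores must be named")
  if (anyNA(object@scores) || any(!is.finite(object@scores)))
    return("scores must be finite")
  TRUE
})

ScoreVector <- function(scores, algorithm, parameters = list(),
                        iterations = 0L) {
  new("ScoreVector", scores = scores, algorithm = algorithm,
      parameters = parameters, iterations = as.integer(iterations))
}

#' Pooled ROC curve and AUC for one leave-one-out run
#'
#' Counts are pooled over all held-out folds of one disease: at threshold
#' tau, \code{tp} is the number of held-out complexes ranked at or better
#' than tau and \code{fp} the number of (fold, candidate) pairs ranked at or
#' better than tau. \code{nPos = |D|} and \code{nNeg = |D| * |C|} so that
#' TP+FN and FP+TN are conserved at every threshold.
#'
#' @slot tau numeric; thresholds swept over every distinct observed rank.
#' @slot tp,fp numeric; pooled counts at each threshold.
#' @slot nPos,nNeg numeric; positive/negative totals.
#' @slot auc numeric; trapezoidal area under the (fpr, sensitivity) curve.
#' @slot heldOutRanks numeric; rank of the held-out complex per fold.
#'
#' @seealso [loocv()], [rocPoints()]
#' @export
setClass("RocResult",
  representation(tau = "numeric", tp = "numeric", fp = "numeric",
                 nPos = "numeric", nNeg = "numeric", auc = "numeric",
                 heldOutRanks = "numeric"))

setValidity("RocResult", function(object) {
  if (length(object@tp) != length(object@tau) ||
      length(object@fp) != length(object@tau))
    return("tp/fp must be parallel to tau")
  if (is.unsorted(object@tp) || is.unsorted(object@fp))
    return("pooled counts must be non-decreasing in tau")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})
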