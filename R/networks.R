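# Construction of the three functional similarity protein-complex networks:
#   shared_elements : |Ci n Cj| / min(|Ci|, |Cj|) over subunit sets
#   shared_go       : same overlap ratio over GO annotation closures,
#                     computed per sub-ontology and integrated by
#                     per-edge average
#   shared_ppi      : mean inverse shortest-path distance between the two
#                     subunit sets in the PPI graph

#' Shared-subunit similarity between two complexes
#'
#' Number of shared subunits normalised by the size of the smaller complex.
#' An interaction exists only when at least one subunit is shared, in which
#' case the weight lies in (0, 1].
#'
#' @param ci,cj character vectors of gene ids (the two complexes' subunits).
#' @return numeric weight in [0, 1]; 0 means no interaction.
#' @examples
#' sharedElementWeight(c("A", "B", "C"), c("B", "C", "D", "E"))  # 2/3
#' @export
sharedElementWeight <- function(ci, cj) {
  ci <- unique(ci); cj <- unique(cj)
  length(intersect(ci, cj)) / min(length(ci), length(cj))
}

#' Shared-GO-term similarity between two complexes
#'
#' Overlap of the two complexes' GO annotation closures (direct terms plus
#' ancestors, roots excluded) normalised by the smaller closure. Both
#' profiles must come from the same sub-ontology. No interaction when either
#' profile is empty.
#'
#' @param pi,pj character vectors: the two closed term sets (see
#'   [complexGoProfile()]).
#' @return numeric weight in [0, 1]; 0 means no interaction.
#' @export
sharedGoWeight <- function(pi, pj) {
  pi <- unique(pi); pj <- unique(pj)
  if (length(pi) == 0L || length(pj) == 0L) return(0)
  length(intersect(pi, pj)) / min(length(pi), length(pj))
}

#' PPI-based similarity between two complexes
#'
#' Mean of 1/SP over all subunit pairs (p, q) with p in ci, q in cj, where
#' SP(p, q) = 1 when p and q are the same gene or both belong to the two
#' complexes' shared subunits, and otherwise is the unweighted shortest-path
#' length between them in the PPI graph. Pairs with no connecting path (or
#' with a gene absent from the PPI) contribute 0, i.e. SP is taken as
#' infinite. The result lies in [0, 1].
#'
#' @param ci,cj character vectors of gene ids.
#' @param ppi an undirected \code{igraph} graph over gene ids (as from
#'   [readPpi()]).
#' @return numeric weight in [0, 1]; 0 means no interaction.
#' @export
ppiComplexWeight <- function(ci, cj, ppi) {
  ci <- unique(ci); cj <- unique(cj)
  genes <- unique(c(ci, cj))
  D <- .ppiDistances(ppi, genes)
  .ppiWeight(ci, cj, D)
}

# full |genes| x |genes| hop-count matrix, Inf where unreachable or absent
.ppiDistances <- function(ppi, genes) {
  D <- matrix(Inf, length(genes), length(genes),
              dimnames = list(genes, genes))
  present <- intersect(genes, igraph::V(ppi)$name)
  if (length(present))
    D[present, present] <- igraph::distances(ppi, v = present, to = present,
                                             algorithm = "unweighted")
  diag(D) <- 1  # the p == q rule
  D
}

.ppiWeight <- function(ci, cj, D) {
  inv <- 1 / D[ci, cj, drop = FALSE]
  shared <- intersect(ci, cj)
  if (length(shared))
    inv[ci %in% shared, cj %in% shared] <- 1  # both endpoints shared
  sum(inv) / (length(ci) * length(cj))
}

#' Integrate weighted networks by per-edge average
#'
#' An edge is present in the integrated network when it is present in at
#' least one input network, and its weight is the mean over only the
#' networks that contain it (denominator M = number of networks containing
#' the edge, not the total number of networks).
#'
#' @param nets non-empty list of [WeightedNetwork-class] objects over the
#'   same id universe.
#' @return a [WeightedNetwork-class]; its node set is the union of the
#'   inputs' node sets.
#' @export
integratePerEdgeAverage <- function(nets) {
  if (!length(nets)) stop("need at least one network to integrate")
  allEdges <- do.call(rbind, lapply(nets, edges))
  allNodes <- sort(unique(unlist(lapply(nets, nodes), use.names = FALSE)))
  if (nrow(allEdges) == 0L)
    return(WeightedNetwork(allEdges, nodes = allNodes))
  key <- paste0(allEdges$from, "\t", allEdges$to)
  w <- vapply(split(allEdges$weight, key), mean, numeric(1))
  ft <- strsplit(names(w), "\t", fixed = TRUE)
  WeightedNetwork(
    data.frame(from = vapply(ft, `[[`, character(1), 1L),
               to = vapply(ft, `[[`, character(1), 2L),
               weight = unname(w), stringsAsFactors = FALSE),
    nodes = allNodes)
}

#' Build a functional similarity protein-complex network
#'
#' Scores every unordered pair of complexes with the similarity of the
#' chosen mode and keeps pairs with positive weight. For
#' \code{"shared_go"}, one network is built per sub-ontology (BP, CC, MF)
#' and the three are combined with [integratePerEdgeAverage()]. Complexes
#' left without any interaction are omitted from the node set unless
#' \code{keepIsolated = TRUE} (so the three modes generally have different
#' node counts).
#'
#' @param complexes a [ComplexSet-class].
#' @param mode similarity mode: \code{"shared_elements"},
#'   \code{"shared_go"} or \code{"shared_ppi"}.
#' @param annotations,dag required for \code{"shared_go"}: annotation table
#'   (see [readGene2go()]) and [GoDag-class].
#' @param ppi required for \code{"shared_ppi"}: \code{igraph} PPI graph.
#' @param keepIsolated keep complexes with no interaction as isolated nodes.
#' @return a [WeightedNetwork-class].
#' @examples
#' cs <- ComplexSet(list(a = c("X", "Y"), b = c("Y", "Z"), c = "Q"))
#' buildNetwork(cs, "shared_elements")           # a-b only
#' buildNetwork(cs, "shared_elements", keepIsolated = TRUE)
#' @export
buildNetwork <- function(complexes,
                         mode = c("shared_elements", "shared_go",
                                  "shared_ppi"),
                         annotations = NULL, dag = NULL, ppi = NULL,
                         keepIsolated = FALSE) {
  mode <- match.arg(mode)
  ids <- complexIds(complexes)
  net <- switch(mode,
    shared_elements = .overlapNetwork(members(complexes)),
    shared_go = {
      if (is.null(annotations) || is.null(dag))
        stop("shared_go mode needs 'annotations' and 'dag'")
      subNets <- lapply(c("BP", "CC", "MF"), function(sub) {
        prof <- complexGoProfiles(complexes, annotations, dag, sub)
        .overlapNetwork(prof[lengths(prof) > 0L])
      })
      integratePerEdgeAverage(subNets)
    },
    shared_ppi = {
      if (is.null(ppi)) stop("shared_ppi mode needs 'ppi'")
      .ppiNetwork(members(complexes), ppi)
    })
  WeightedNetwork(edges(net), nodes = if (keepIsolated) ids else NULL)
}

# overlap-ratio network over a named list of sets, via an inverted index so
# only pairs with non-empty intersection are visited
.overlapNetwork <- function(sets) {
  if (length(sets) < 2L)
    return(WeightedNetwork(data.frame(from = character(),
                                      to = character(), weight = numeric())))
  ids <- names(sets)
  sizes <- lengths(sets)
  item2set <- split(rep(ids, sizes), unlist(sets, use.names = FALSE))
  pairs <- unique(do.call(rbind, lapply(item2set, function(s) {
    if (length(s) < 2L) return(NULL)
    s <- sort(s)
    t(utils::combn(s, 2L))
  })))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(WeightedNetwork(data.frame(from = character(),
                                      to = character(), weight = numeric())))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- sets[[pairs[r, 1L]]]; b <- sets[[pairs[r, 2L]]]
    length(intersect(a, b)) / min(length(a), length(b))
  }, numeric(1))
  WeightedNetwork(data.frame(from = pairs[, 1L], to = pairs[, 2L],
                             weight = w, stringsAsFactors = FALSE))
}

.ppiNetwork <- function(mem, ppi) {
  ids <- names(mem)
  genes <- unique(unlist(mem, use.names = FALSE))
  D <- .ppiDistances(ppi, genes)
  n <- length(ids)
  from <- character(); to <- character(); weight <- numeric()
  if (n >= 2L) {
    res <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      wi <- vapply((i + 1L):n, function(j)
        .ppiWeight(mem[[i]], mem[[j]], D), numeric(1))
      keep <- wi > 0
      if (any(keep))
        res[[i]] <- data.frame(from = ids[i], to = ids[(i + 1L):n][keep],
                               weight = wi[keep], stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, res)
    if (!is.null(res)) {
      from <- res$from; to <- res$to; weight <- res$weight
    }
  }
  WeightedNetwork(data.frame(from = from, to = to, weight = weight,
                             stringsAsFactors = FALSE))
}

#' Threshold a weighted network
#'
#' Keeps edges with weight at least \code{t}; nodes left without any edge
#' are dropped. Used to extract sparser networks from the near-complete GO
#' and PPI similarity networks.
#'
#' @param net a [WeightedNetwork-class].
#' @param t threshold in [0, 1].
#' @return a [WeightedNetwork-class].
#' @export
thresholdNetwork <- function(net, t) {
  stopifnot(t >= 0, t <= 1)
  e <- edges(net)
  WeightedNetwork(e[e$weight >= t, , drop = FALSE])
}

#' Basic size and density statistics of a network
#'
#' @param net a [WeightedNetwork-class].
#' @return list with elements \code{nodes}, \code{edges} and \code{density}
#'   (\code{2|E| / (|V| (|V|-1))}, 0 for fewer than two nodes).
#' @export
networkStats <- function(net) {
  v <- numNodes(net); e <- numEdges(net)
  list(nodes = v, edges = e,
       density = if (v < 2L) 0 else 2 * e / (v * (v - 1)))
}
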