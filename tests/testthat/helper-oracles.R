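# Independent oracles and small random fixture builders. Everything here is
# deliberately brute-force and shares no code path with the package: plain
# loops, dense matrices and base solve().

# random undirected weighted network over letter-ish node ids
randomNetwork <- function(nNodes, p = 0.4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(nNodes))
  from <- character(); to <- character(); w <- numeric()
  for (i in seq_len(nNodes - 1)) {
    for (j in (i + 1):nNodes) {
      if (runif(1) < p) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        w <- c(w, round(runif(1, 0.05, 1), 3))
      }
    }
  }
  WeightedNetwork(data.frame(from = from, to = to, weight = w),
                  nodes = ids)
}

# dense symmetric weight matrix straight from the edge table
denseAdjacency <- function(net) {
  ids <- nodes(net)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- edges(net)
  for (r in seq_len(nrow(e))) {
    W[e$from[r], e$to[r]] <- e$weight[r]
    W[e$to[r], e$from[r]] <- e$weight[r]
  }
  W
}

# NBH by an explicit (node, seed) double loop
oracleNbh <- function(net, seeds) {
  W <- denseAdjacency(net)
  vapply(nodes(net), function(v) {
    tot <- 0
    for (s in seeds) tot <- tot + W[v, s]
    tot
  }, numeric(1))
}

# closed-form steady states: P = (I - c1 * M)^-1 c2 P0 with M the
# column-oriented propagation operator, built here from scratch
oracleSteadyState <- function(net, seeds, algorithm, param) {
  W <- denseAdjacency(net)
  n <- nrow(W)
  p0 <- numeric(n); names(p0) <- nodes(net)
  p0[seeds] <- 1 / length(seeds)
  if (algorithm == "rwr") {
    d <- rowSums(W)
    Wrow <- W
    for (i in seq_len(n)) if (d[i] > 0) Wrow[i, ] <- W[i, ] / d[i]
    M <- t(Wrow)
    c1 <- 1 - param; c2 <- param
  } else {
    d <- rowSums(W)
    Ws <- W
    for (i in seq_len(n)) for (j in seq_len(n))
      if (W[i, j] > 0) Ws[i, j] <- W[i, j] / sqrt(d[i] * d[j])
    M <- Ws
    c1 <- param; c2 <- 1 - param
  }
  p <- solve(diag(n) - c1 * M, c2 * p0)
  names(p) <- nodes(net)
  p
}

# BFS hop distances from one source over an undirected edge list
oracleBfsDistances <- function(edgeList, source, genes) {
  adj <- list()
  for (r in seq_len(nrow(edgeList))) {
    a <- edgeList[r, 1]; b <- edgeList[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- rep(Inf, length(genes)); names(dist) <- genes
  if (!source %in% genes) return(dist)
  dist[source] <- 0
  frontier <- source
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (u %in% genes && is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# the PPI similarity by explicit double loop over subunit pairs
oraclePpiWeight <- function(ci, cj, edgeList) {
  genes <- unique(c(ci, cj, as.vector(edgeList)))
  shared <- intersect(ci, cj)
  total <- 0
  for (p in ci) {
    d <- oracleBfsDistances(edgeList, p, genes)
    for (q in cj) {
      sp <- if (p == q || (p %in% shared && q %in% shared)) 1 else d[[q]]
      if (is.finite(sp) && sp > 0) total <- total + 1 / sp
    }
  }
  total / (length(ci) * length(cj))
}

# tie-corrected Mann-Whitney AUC by O(n^2) pairwise comparison: the
# probability that a held-out rank beats (is smaller than) a candidate rank
oracleMannWhitney <- function(heldOutRanks, candidateRanks) {
  tot <- 0
  for (h in heldOutRanks) {
    for (c in candidateRanks) {
      tot <- tot + (h < c) + 0.5 * (h == c)
    }
  }
  tot / (length(heldOutRanks) * length(candidateRanks))
}

# brute-force ancestor closure by repeated one-step parent expansion
oracleAncestors <- function(parents, term, roots) {
  anc <- character()
  frontier <- parents[[term]]
  while (length(frontier)) {
    anc <- unique(c(anc, frontier))
    frontier <- setdiff(unique(unlist(parents[frontier],
                                      use.names = FALSE)), anc)
  }
  setdiff(anc, roots)
}

# random parent-list DAG: term i may point at any earlier term
randomDagParents <- function(nTerms, seed, rootId = "GO:0008150") {
  set.seed(seed)
  ids <- c(rootId, sprintf("T%03d", seq_len(nTerms - 1)))
  parents <- list()
  parents[[rootId]] <- character()
  for (i in 2:nTerms) {
    k <- sample(1:min(2, i - 1), 1)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], k)
  }
  parents
}

# a small complex set with guaranteed overlaps
randomComplexSet <- function(nComplexes, nGenes, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  mem <- lapply(seq_len(nComplexes), function(i)
    sample(genes, sample(2:min(6, nGenes), 1)))
  names(mem) <- sprintf("c%02d", seq_len(nComplexes))
  ComplexSet(mem)
}

smallBundle <- function(seed = 5, cohesion = 1) {
  generateSyntheticData(syntheticConfig(
    nGenes = 80, nComplexes = 16, nClusters = 4, nDiseases = 4,
    genesPerDisease = 3, nGoTerms = 12, dagDepth = 3,
    cohesion = cohesion, seed = seed))
}
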