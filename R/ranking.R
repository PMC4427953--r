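# Candidate ranking against a seed set: the parameter-free neighborhood
# score (NBH) and the two propagation algorithms (RWR, PRINCE).
#
# Propagation orientation: both algorithms iterate
#   P[t+1] = c1 * t(W') P[t] + c2 * P0
# where W' is the (row-)normalized operator of the algorithm. Multiplying
# by the transpose makes probability mass leave each node along its own
# normalized out-weights — the walker semantics — rather than mixing
# in-flows and out-flows.

#' Neighborhood (NBH) score
#'
#' The score of a node is the sum of the weights of its edges to seed
#' (source) nodes; nodes with no seed neighbor score 0. Parameter-free and
#' purely local. Seed nodes themselves are scored by the same formula —
#' excluding them from the candidate set is the evaluator's job.
#'
#' @param net a [WeightedNetwork-class].
#' @param seeds non-empty character vector of seed node ids, all present in
#'   the network.
#' @return a [ScoreVector-class] over all network nodes.
#' @examples
#' net <- WeightedNetwork(data.frame(from = c("s", "s"), to = c("v", "u"),
#'                                   weight = c(0.3, 0.5)))
#' scores(nbhScore(net, "s"))
#' @export
nbhScore <- function(net, seeds) {
  .checkSeeds(net, seeds)
  A <- adjacencyMatrix(net)
  p <- Matrix::rowSums(A[, seeds, drop = FALSE])
  names(p) <- nodes(net)
  ScoreVector(p, "nbh")
}

.checkSeeds <- function(net, seeds) {
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  missing <- setdiff(seeds, nodes(net))
  if (length(missing))
    stop("seed(s) not in network: ", paste(missing, collapse = ", "))
  if (anyDuplicated(seeds)) stop("duplicate seed ids")
}

#' Random-walk transition operator
#'
#' Row-normalizes the adjacency matrix: entry (i, j) is the probability that
#' a walker at node i steps to node j. Rows of isolated nodes are all zero
#' (dangling: mass reaching them is lost).
#'
#' @param net a [WeightedNetwork-class].
#' @return a sparse row-stochastic matrix (zero rows allowed).
#' @export
rwrTransition <- function(net) {
  A <- adjacencyMatrix(net)
  d <- Matrix::rowSums(A)
  inv <- ifelse(d > 0, 1 / d, 0)
  W <- Matrix::Diagonal(x = inv) %*% A
  dimnames(W) <- dimnames(A)
  W
}

#' PRINCE symmetric normalization
#'
#' Divides each weight by the square root of the product of its endpoints'
#' weighted degrees: W'_ij = W_ij / sqrt(deg(i) * deg(j)). The operator is
#' symmetric with spectral radius at most 1, which guarantees convergence of
#' the PRINCE iteration for any trade-off alpha < 1.
#'
#' @param net a [WeightedNetwork-class].
#' @return a sparse symmetric matrix.
#' @export
princeNormalize <- function(net) {
  A <- adjacencyMatrix(net)
  d <- Matrix::rowSums(A)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(x = inv)
  W <- Dm %*% A %*% Dm
  dimnames(W) <- dimnames(A)
  W
}

# restart distribution: 1/|S| on seeds, 0 elsewhere
.seedPrior <- function(net, seeds) {
  p0 <- numeric(numNodes(net))
  names(p0) <- nodes(net)
  p0[seeds] <- 1 / length(seeds)
  p0
}

.propagate <- function(op, p0, smooth, prior, tol = 1e-6,
                       maxIterations = 10000L) {
  p <- p0
  for (iter in seq_len(maxIterations)) {
    pNew <- as.numeric(smooth * (op %*% p)) + prior * p0
    delta <- sum(abs(pNew - p))
    p <- pNew
    if (delta < tol) {
      names(p) <- names(p0)
      return(list(p = p, iterations = iter))
    }
  }
  stop(sprintf(
    "propagation did not converge after %d iterations (L1 residual %.3g)",
    maxIterations, delta))
}

#' Random walk with restart (RWR) score
#'
#' Iterates \code{P[t+1] = (1 - gamma) * t(W') P[t] + gamma * P0} from the
#' seed prior P0 (1/|S| on each seed) until the L1 change drops below
#' \code{tol}, where W' is the row-normalized transition operator of
#' [rwrTransition()] and gamma is the restart (back-) probability. Nodes in
#' components without a seed receive zero mass.
#'
#' @param net a [WeightedNetwork-class].
#' @param seeds non-empty character vector of seed ids in the network.
#' @param gamma restart probability in (0, 1).
#' @param tol L1 convergence threshold (default 1e-6).
#' @param maxIterations iteration cap; exceeding it is an error.
#' @return a [ScoreVector-class]; steady-state probabilities over all nodes.
#' @export
rwrScore <- function(net, seeds, gamma, tol = 1e-6, maxIterations = 10000L) {
  stopifnot(gamma > 0, gamma < 1)
  .checkSeeds(net, seeds)
  op <- Matrix::t(rwrTransition(net))
  p0 <- .seedPrior(net, seeds)
  res <- .propagate(op, p0, smooth = 1 - gamma, prior = gamma,
                    tol = tol, maxIterations = maxIterations)
  ScoreVector(res$p, "rwr", list(gamma = gamma), res$iterations)
}

#' PRINCE propagation score
#'
#' Iterates \code{P[t+1] = alpha * W' P[t] + (1 - alpha) * P0} with the
#' symmetric normalization of [princeNormalize()] (W' symmetric, so the
#' walker orientation is immaterial here), seed prior as in [rwrScore()],
#' and trade-off alpha weighing network smoothing against the prior.
#'
#' @inheritParams rwrScore
#' @param alpha trade-off parameter in (0, 1); larger means more smoothing.
#' @return a [ScoreVector-class].
#' @export
princeScore <- function(net, seeds, alpha, tol = 1e-6,
                        maxIterations = 10000L) {
  stopifnot(alpha > 0, alpha < 1)
  .checkSeeds(net, seeds)
  op <- princeNormalize(net)
  p0 <- .seedPrior(net, seeds)
  res <- .propagate(op, p0, smooth = alpha, prior = 1 - alpha,
                    tol = tol, maxIterations = maxIterations)
  ScoreVector(res$p, "prince", list(alpha = alpha), res$iterations)
}

#' Rank candidates by score
#'
#' Restricts a score vector to a candidate set, sorts by descending score
#' and assigns midranks to ties (so the rank sum is always n(n+1)/2).
#' Candidates absent from the score vector (e.g. complexes outside the
#' network) are scored 0.
#'
#' @param sv a [ScoreVector-class] (or a named numeric vector of scores).
#' @param candidates character vector of node ids to rank.
#' @return data.frame with columns \code{id}, \code{score}, \code{rank},
#'   ordered by increasing rank (ties in rank ordered by id).
#' @examples
#' sv <- nbhScore(WeightedNetwork(data.frame(
#'   from = "s", to = "v", weight = 0.7)), "s")
#' rankScores(sv, c("v", "w"))  # w is unscored, hence 0
#' @export
rankScores <- function(sv, candidates) {
  s <- if (methods::is(sv, "ScoreVector")) scores(sv) else sv
  if (anyDuplicated(candidates)) stop("duplicate candidate ids")
  sc <- numeric(length(candidates))
  names(sc) <- candidates
  hit <- intersect(candidates, names(s))
  sc[hit] <- s[hit]
  rk <- rank(-sc, ties.method = "average")
  out <- data.frame(id = candidates, score = unname(sc), rank = unname(rk),
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$id), , drop = FALSE]
}
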