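# Leave-one-out cross-validation with pooled-count ROC/AUC, Welch t-test
# comparison of AUC samples, and the random-set case-study baseline.

# run a scoring algorithm; seeds outside the network are ignored, and if no
# seed is in the network every node scores 0 (the fold is uninformative)
.scoreFold <- function(net, seeds, algorithm, gamma, alpha) {
  seedsIn <- intersect(seeds, nodes(net))
  if (length(seedsIn) == 0L) {
    z <- numeric(numNodes(net))
    names(z) <- nodes(net)
    return(z)
  }
  sv <- switch(algorithm,
    nbh = nbhScore(net, seedsIn),
    rwr = rwrScore(net, seedsIn, gamma = gamma),
    prince = princeScore(net, seedsIn, alpha = alpha),
    stop("unknown algorithm: ", algorithm))
  scores(sv)
}

#' Pooled-count ROC curve from held-out and candidate ranks
#'
#' Pools TP/FN counts over the held-out ranks and FP/TN counts over the
#' candidate ranks, sweeping the rank threshold tau over every distinct
#' observed rank value. Sweeping observed ranks (rather than only the
#' integers) keeps the trapezoidal AUC exactly equal to the tie-corrected
#' Mann-Whitney statistic when midranks occur; with integer ranks the two
#' sweeps coincide.
#'
#' @param heldOutRanks numeric vector: the rank of the held-out complex in
#'   each fold (one per fold).
#' @param candidateRanks numeric vector: all pooled candidate ranks across
#'   folds.
#' @return a [RocResult-class].
#' @export
pooledRoc <- function(heldOutRanks, candidateRanks) {
  nPos <- length(heldOutRanks)
  nNeg <- length(candidateRanks)
  tau <- sort(unique(c(heldOutRanks, candidateRanks)))
  hs <- sort(heldOutRanks)
  cs <- sort(candidateRanks)
  tp <- findInterval(tau, hs)   # I(rank <= tau), counts
  fp <- findInterval(tau, cs)
  x <- c(0, fp / nNeg)
  y <- c(0, tp / nPos)
  aucVal <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  new("RocResult", tau = tau, tp = as.numeric(tp), fp = as.numeric(fp),
      nPos = nPos, nNeg = nNeg, auc = aucVal,
      heldOutRanks = heldOutRanks)
}

#' Leave-one-out cross-validation for one disease
#'
#' Each known disease-associated complex s in \code{seedComplexes} is held
#' out in turn; the remaining seeds become the source set, the algorithm
#' scores the network, and the candidates \code{C union \{s\}} are ranked,
#' where C is all network nodes not known to be associated with the disease
#' (fixed across folds). TP/FN counts are pooled over the held-out ranks
#' and FP/TN over all (fold, candidate) ranks; sweeping the rank threshold
#' yields the ROC curve and its trapezoidal AUC.
#'
#' @param net a [WeightedNetwork-class].
#' @param seedComplexes character vector of at least two known associated
#'   complex ids (ids outside the network are tolerated: such folds rank a
#'   zero-scored held-out complex).
#' @param algorithm \code{"nbh"}, \code{"rwr"} or \code{"prince"}.
#' @param gamma,alpha propagation parameters for RWR / PRINCE.
#' @param candidates optional explicit candidate pool; defaults to
#'   \code{setdiff(nodes(net), seedComplexes)}.
#' @return a [RocResult-class].
#' @export
loocv <- function(net, seedComplexes,
                  algorithm = c("nbh", "rwr", "prince"),
                  gamma = 0.9, alpha = 0.1, candidates = NULL) {
  algorithm <- match.arg(algorithm)
  D <- unique(seedComplexes)
  if (length(D) < 2L)
    stop("leave-one-out needs at least two seed complexes")
  if (is.null(candidates)) candidates <- setdiff(nodes(net), D)
  if (length(candidates) == 0L)
    stop("empty candidate set")
  heldRanks <- numeric(length(D))
  candRanks <- vector("list", length(D))
  for (i in seq_along(D)) {
    s <- D[[i]]
    sc <- .scoreFold(net, setdiff(D, s), algorithm, gamma, alpha)
    rk <- rankScores(sc, c(candidates, s))
    heldRanks[[i]] <- rk$rank[match(s, rk$id)]
    candRanks[[i]] <- rk$rank[match(candidates, rk$id)]
  }
  pooledRoc(heldRanks, unlist(candRanks, use.names = FALSE))
}

#' LOOCV over many diseases and a parameter grid
#'
#' Runs [loocv()] for every disease profile and every parameter value, and
#' summarises mean and standard deviation (n-1 denominator) of the AUC per
#' parameter value. NBH has no parameter and yields a single column.
#'
#' @param net a [WeightedNetwork-class].
#' @param profiles named list: disease id -> seed complex ids (each of
#'   length >= 2; see [filterDiseasesMinSeeds()]).
#' @param algorithm \code{"nbh"}, \code{"rwr"} or \code{"prince"}.
#' @param params numeric vector of gamma (RWR) or alpha (PRINCE) values;
#'   ignored for NBH.
#' @return list with \code{perDisease} (data.frame: disease_id, n_seeds,
#'   param, auc) and \code{summary} (data.frame: param, mean_auc, sd_auc,
#'   n_diseases).
#' @export
evaluateSuite <- function(net, profiles,
                          algorithm = c("nbh", "rwr", "prince"),
                          params = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "nbh") params <- NA_real_
  if (is.null(params))
    stop("propagation algorithms need a parameter grid")
  rows <- list()
  for (p in params) {
    for (d in names(profiles)) {
      roc <- loocv(net, profiles[[d]], algorithm,
                   gamma = if (is.na(p)) 0.9 else p,
                   alpha = if (is.na(p)) 0.1 else p)
      rows[[length(rows) + 1L]] <- data.frame(
        disease_id = d, n_seeds = length(profiles[[d]]),
        param = p, auc = auc(roc), stringsAsFactors = FALSE)
    }
  }
  perDisease <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(params, function(p) {
    df <- perDisease[if (is.na(p)) is.na(perDisease$param) else
      !is.na(perDisease$param) & perDisease$param == p, , drop = FALSE]
    data.frame(param = p, mean_auc = mean(df$auc),
               sd_auc = stats::sd(df$auc), n_diseases = nrow(df))
  }))
  rownames(summary) <- NULL
  list(perDisease = perDisease, summary = summary)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test for a difference in means assuming unequal variances
#' (Welch statistic with Welch-Satterthwaite degrees of freedom), as used to
#' compare per-disease AUC samples between algorithms or networks. Two
#' samples with equal means and zero variance give t = 0, p = 1.
#'
#' @param a,b numeric vectors (e.g. per-disease AUC values).
#' @return list with \code{t}, \code{df} and \code{p}.
#' @export
welchTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  se2 <- va + vb
  dm <- mean(a) - mean(b)
  if (se2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    return(list(t = t, df = na + nb - 2,
                p = if (dm == 0) 1 else 0))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Random-set baseline for a top-k case study
#'
#' Draws \code{nSets} uniform without-replacement sets of \code{k} nodes
#' from the network's node set, counts "hits" per set (nodes satisfying the
#' predicate, e.g. complexes containing a gene with literature evidence),
#' and — when an observed top-k hit count is supplied — runs a two-sided
#' one-sample t-test of the null that the random-set mean equals it.
#'
#' @param netNodes character vector: the node universe to draw from.
#' @param hits either a character vector of hit node ids or a predicate
#'   function mapping a node id to TRUE/FALSE.
#' @param k set size (at most \code{length(netNodes)}).
#' @param nSets number of random sets (default 200).
#' @param observed optional observed hit count among the true top-k.
#' @param seed RNG seed for the draws (default 42); the global RNG state is
#'   restored afterwards.
#' @return list with \code{counts} (per-set hit counts), \code{mean},
#'   and, if \code{observed} given, \code{t} and \code{p}.
#' @export
randomSetBaseline <- function(netNodes, hits, k, nSets = 200,
                              observed = NULL, seed = 42) {
  if (k > length(netNodes))
    stop("k exceeds the number of available nodes")
  isHit <- if (is.function(hits)) {
    vapply(netNodes, hits, logical(1))
  } else {
    netNodes %in% hits
  }
  counts <- .withSeed(seed, {
    vapply(seq_len(nSets), function(i)
      sum(isHit[sample.int(length(netNodes), k)]), numeric(1))
  })
  out <- list(counts = counts, mean = mean(counts))
  if (!is.null(observed)) {
    s <- stats::sd(counts)
    if (s == 0) {
      out$t <- if (out$mean == observed) 0 else
        sign(out$mean - observed) * Inf
      out$p <- if (out$mean == observed) 1 else 0
    } else {
      tt <- stats::t.test(counts, mu = observed)
      out$t <- unname(tt$statistic)
      out$p <- tt$p.value
    }
  }
  out
}

#' Top-k nodes of a ranking
#'
#' First k entries by rank; ties spanning the k boundary are cut
#' deterministically by lexicographic node id (the order [rankScores()]
#' already produces).
#'
#' @param ranking data.frame as returned by [rankScores()].
#' @param k how many nodes to return (0 gives an empty vector).
#' @return character vector of node ids.
#' @export
topK <- function(ranking, k) {
  stopifnot(k >= 0)
  utils::head(ranking$id, k)
}

# evaluate expr under a fixed RNG seed, restoring the global state after
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
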