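# The three similarity weights, network assembly, integration, thresholds.

test_that("shared-subunit weight follows |intersection| / min size", {
  expect_equal(sharedElementWeight(c("A", "B", "C"), c("B", "C", "D", "E")),
               2 / 3)
  expect_equal(sharedElementWeight(c("A", "B"), c("A", "B", "C")), 1)
  expect_equal(sharedElementWeight(c("A", "B"), c("X", "Y")), 0)
})

test_that("shared-GO weight handles empty profiles", {
  expect_equal(sharedGoWeight(c("t1", "t2"), c("t1", "t2")), 1)
  expect_equal(sharedGoWeight(c("t1", "t2"), c("t2", "t3", "t4")), 1 / 2)
  expect_equal(sharedGoWeight(character(), c("t1")), 0)
})

test_that("overlap weights are symmetric and match a set oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    u <- sprintf("x%02d", 1:12)
    a <- sample(u, sample(2:6, 1))
    b <- sample(u, sample(2:6, 1))
    brute <- sum(!is.na(match(unique(a), unique(b)))) /
      min(length(unique(a)), length(unique(b)))
    expect_identical(sharedElementWeight(a, b), brute)
    expect_identical(sharedElementWeight(b, a), brute)
    expect_identical(sharedGoWeight(a, b), brute)
  }
})

test_that("PPI weight applies the SP special cases", {
  # identical membership under different ids: all pairs SP = 1
  ppi <- igraph::make_graph(c("A", "X", "X", "B"), directed = FALSE)
  expect_equal(ppiComplexWeight(c("A", "B"), c("A", "B"), ppi), 1)
  # single pair two hops apart
  expect_equal(ppiComplexWeight("A", "B", ppi), 0.5)
  # disconnected pair contributes zero
  ppi2 <- igraph::make_graph(c("A", "X", "B", "Y"), directed = FALSE)
  expect_equal(ppiComplexWeight("A", "B", ppi2), 0)
  # shared-pair rule wins even when the genes are absent from the PPI
  expect_equal(ppiComplexWeight(c("Q", "R"), c("Q", "R"), ppi), 1)
})

test_that("PPI weight equals a BFS double-loop oracle on random graphs", {
  for (seed in 1:12) {
    set.seed(seed)
    genes <- sprintf("p%02d", 1:20)
    ne <- sample(10:30, 1)
    el <- cbind(sample(genes, ne, replace = TRUE),
                sample(genes, ne, replace = TRUE))
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    ppi <- igraph::simplify(
      igraph::graph_from_edgelist(el, directed = FALSE))
    ci <- sample(genes, sample(2:5, 1))
    cj <- sample(genes, sample(2:5, 1))
    got <- ppiComplexWeight(ci, cj, ppi)
    want <- oraclePpiWeight(ci, cj, el)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(ppiComplexWeight(cj, ci, ppi), got, tolerance = 1e-12)
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("per-edge average divides by the number of networks with the edge", {
  n1 <- WeightedNetwork(data.frame(from = "a", to = "b", weight = 0.4))
  n2 <- WeightedNetwork(data.frame(from = c("a", "a"), to = c("b", "c"),
                                   weight = c(0.6, 0.9)))
  n3 <- WeightedNetwork(data.frame(from = "b", to = "c", weight = 0.2))
  out <- integratePerEdgeAverage(list(n1, n2, n3))
  e <- edges(out)
  expect_equal(e$weight[e$from == "a" & e$to == "b"], 0.5)  # M = 2
  expect_equal(e$weight[e$from == "a" & e$to == "c"], 0.9)  # M = 1
  expect_equal(e$weight[e$from == "b" & e$to == "c"], 0.2)
  # all three share an edge
  mk <- function(w) WeightedNetwork(data.frame(from = "x", to = "y",
                                               weight = w))
  expect_equal(edges(integratePerEdgeAverage(
    list(mk(0.2), mk(0.4), mk(0.9))))$weight, 0.5)
  # idempotence when all networks agree
  expect_equal(edges(integratePerEdgeAverage(
    list(mk(0.7), mk(0.7))))$weight, 0.7)
  expect_error(integratePerEdgeAverage(list()), "at least one")
})

test_that("network building omits isolated complexes unless asked", {
  cs <- ComplexSet(list(a = c("X", "Y"), b = c("Y", "Z"), c = c("X", "Z"),
                        d = "Q"))
  net <- buildNetwork(cs, "shared_elements")
  expect_equal(numEdges(net), 3)  # pairwise-sharing triangle
  expect_setequal(nodes(net), c("a", "b", "c"))  # d drops out
  full <- buildNetwork(cs, "shared_elements", keepIsolated = TRUE)
  expect_setequal(nodes(full), c("a", "b", "c", "d"))
  expect_equal(numEdges(full), 3)
})

test_that("every built network matches exhaustive pairwise scoring", {
  b <- smallBundle(seed = 21)
  cs <- b$complexes
  ids <- complexIds(cs)
  mem <- members(cs)
  net <- buildNetwork(cs, "shared_elements", keepIsolated = TRUE)
  A <- as.matrix(adjacencyMatrix(net))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      expect_equal(A[ids[i], ids[j]],
                   sharedElementWeight(mem[[i]], mem[[j]]))
    }
  }
})

test_that("GO-mode network equals the per-edge average of sub-ontologies", {
  b <- smallBundle(seed = 8)
  whole <- buildNetwork(b$complexes, "shared_go",
                        annotations = b$annotations, dag = b$dag)
  parts <- lapply(c("BP", "CC", "MF"), function(sub) {
    prof <- complexGoProfiles(b$complexes, b$annotations, b$dag, sub)
    prof <- prof[lengths(prof) > 0]
    ids <- names(prof)
    rows <- list()
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i >= j) next
        w <- sharedGoWeight(prof[[i]], prof[[j]])
        if (w > 0)
          rows[[length(rows) + 1]] <- data.frame(
            from = ids[i], to = ids[j], weight = w)
      }
    }
    WeightedNetwork(do.call(rbind, rows))
  })
  manual <- integratePerEdgeAverage(parts)
  em <- edges(manual); ew <- edges(whole)
  expect_equal(ew$from, em$from)
  expect_equal(ew$to, em$to)
  expect_equal(ew$weight, em$weight, tolerance = 1e-12)
})

test_that("thresholding keeps weight >= t and nests monotonically", {
  net <- WeightedNetwork(data.frame(
    from = c("a", "a", "b"), to = c("b", "c", "c"),
    weight = c(0.1, 0.5, 0.9)))
  expect_equal(numEdges(thresholdNetwork(net, 0)), 3)
  t5 <- thresholdNetwork(net, 0.5)
  expect_equal(numEdges(t5), 2)  # >= comparison keeps the 0.5 edge
  expect_equal(numEdges(thresholdNetwork(net, 1)), 0)
  # dropped nodes
  expect_setequal(nodes(thresholdNetwork(net, 0.9)), c("b", "c"))
  # nesting across a grid
  big <- randomNetwork(12, 0.5, seed = 30)
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  edgeKey <- function(n) paste(edges(n)$from, edges(n)$to)
  keys <- lapply(grid, function(t) edgeKey(thresholdNetwork(big, t)))
  for (i in seq_len(length(grid) - 1))
    expect_true(all(keys[[i + 1]] %in% keys[[i]]))
})

test_that("network statistics follow the density formula", {
  tri <- WeightedNetwork(data.frame(from = c("a", "a", "b"),
                                    to = c("b", "c", "c"), weight = 1))
  expect_equal(networkStats(tri)$density, 1)
  path <- WeightedNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
                                     weight = 1))
  expect_equal(networkStats(path)$density, 2 / 3)
  empty <- WeightedNetwork(
    data.frame(from = character(), to = character(), weight = numeric()),
    nodes = c("a", "b", "c", "d"))
  expect_equal(networkStats(empty)$density, 0)
})
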