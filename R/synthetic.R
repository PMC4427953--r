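# Planted-module synthetic data: complexes with overlapping membership
# around gene clusters, a small three-root GO DAG with cluster-coherent
# annotations, a sparse PPI graph densified within clusters, and disease
# gene sets whose cohesion parameter controls how strongly a disease's
# genes concentrate in one cluster (hence how tightly its seed complexes
# cluster in the similarity networks).

#' Configuration for the synthetic data generator
#'
#' Defaults describe a small but structured study: 500 genes in clusters of
#' ~20, 150 complexes of 3-8 subunits drawn mostly from one anchor cluster
#' with geometric rank decay (so same-cluster complexes share their cluster's
#' core genes), a GO DAG with three roots, a sparse background PPI densified
#' within clusters, and 20 diseases of 4 genes each.
#'
#' @param nGenes number of genes.
#' @param nComplexes number of protein complexes.
#' @param complexSizeRange integer length-2: min/max complex size.
#' @param overlapRate probability that a complex member is drawn from the
#'   complex's anchor cluster (the rest leak uniformly from all genes);
#'   drives membership overlap between same-cluster complexes.
#' @param nClusters number of gene clusters (anchor pools).
#' @param nGoTerms number of non-root GO terms per sub-ontology.
#' @param dagDepth number of levels below each root.
#' @param annotationRate probability that a gene carries its cluster's GO
#'   signature in a given sub-ontology.
#' @param ppiEdgeProb background PPI edge probability (Erdos-Renyi);
#'   within-cluster pairs additionally get edges at 10x this rate (capped
#'   at 0.2).
#' @param nDiseases number of disease phenotypes.
#' @param genesPerDisease genes per disease.
#' @param cohesion planted-module cohesion in [0, 1]: the probability that
#'   each disease gene is drawn from the disease's anchor cluster core
#'   (cohesion 1 plants a tight module; cohesion 0 scatters the genes
#'   uniformly).
#' @param seed RNG seed; all generator randomness flows through it.
#' @return a list of validated settings (class \code{syntheticConfig}).
#' @export
syntheticConfig <- function(nGenes = 500, nComplexes = 150,
                            complexSizeRange = c(3L, 8L),
                            overlapRate = 0.85, nClusters = NULL,
                            nGoTerms = 40, dagDepth = 4,
                            annotationRate = 0.7, ppiEdgeProb = 0.01,
                            nDiseases = 20, genesPerDisease = 4,
                            cohesion = 1, seed = 1) {
  if (is.null(nClusters)) nClusters <- max(2L, nGenes %/% 20L)
  stopifnot(nGenes >= 2, nComplexes >= 2,
            length(complexSizeRange) == 2L,
            complexSizeRange[1] >= 1,
            complexSizeRange[2] >= complexSizeRange[1],
            nClusters >= 1, nGoTerms >= dagDepth, dagDepth >= 1,
            nDiseases >= 1, genesPerDisease >= 1,
            genesPerDisease <= nGenes)
  for (p in c(overlapRate, annotationRate, ppiEdgeProb, cohesion))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (complexSizeRange[2] > nGenes)
    stop("maximum complex size exceeds the number of genes")
  cfg <- list(nGenes = nGenes, nComplexes = nComplexes,
              complexSizeRange = as.integer(complexSizeRange),
              overlapRate = overlapRate, nClusters = as.integer(nClusters),
              nGoTerms = nGoTerms, dagDepth = dagDepth,
              annotationRate = annotationRate, ppiEdgeProb = ppiEdgeProb,
              nDiseases = nDiseases, genesPerDisease = genesPerDisease,
              cohesion = cohesion, seed = seed)
  class(cfg) <- "syntheticConfig"
  cfg
}

# sample `size` distinct genes: in-cluster picks use geometric rank decay
# over the (fixed) cluster pool order, leak picks are uniform over all genes
.sampleMembers <- function(size, pool, allGenes, inRate, decay = 0.8) {
  w <- decay^(seq_along(pool) - 1L)
  picked <- character(0)
  guard <- 0L
  while (length(picked) < size && (guard <- guard + 1L) < 1000L) {
    g <- if (stats::runif(1) < inRate) {
      sample(pool, 1L, prob = w)
    } else {
      allGenes[[sample.int(length(allGenes), 1L)]]
    }
    if (!g %in% picked) picked <- c(picked, g)
  }
  picked
}

.makeDag <- function(nGoTerms, dagDepth) {
  rootIds <- c(BP = "GO:0008150", CC = "GO:0005575", MF = "GO:0003674")
  parents <- list(); namespace <- character()
  counter <- 0L
  for (si in seq_along(rootIds)) {
    sub <- names(rootIds)[[si]]
    root <- rootIds[[si]]
    parents[[root]] <- character()
    namespace[[root]] <- sub
    perLevel <- diff(round(seq(0, nGoTerms, length.out = dagDepth + 1L)))
    perLevel[perLevel == 0L] <- 1L
    prev <- root
    for (lvl in seq_len(dagDepth)) {
      ids <- sprintf("GO:9%01d%02d%03d", si, lvl,
                     counter + seq_len(perLevel[[lvl]]))
      counter <- counter + perLevel[[lvl]]
      for (id in ids) {
        nPar <- min(length(prev), sample(1:2, 1L))
        parents[[id]] <- sample(prev, nPar)
        namespace[[id]] <- sub
      }
      prev <- ids
    }
  }
  GoDag(parents, rootIds, namespace = namespace)
}

#' Generate a synthetic study bundle
#'
#' Produces all five inputs the pipeline needs, deterministically under the
#' configured seed: a [ComplexSet-class], a gene2go-style annotation table,
#' a [GoDag-class], an \code{igraph} PPI graph, and disease -> gene
#' assignments. Diseases anchor a gene cluster; with probability
#' \code{cohesion} each disease gene is drawn from that cluster's core (the
#' same geometric-decay pool the cluster's complexes draw from), so at
#' cohesion 1 the disease's seed complexes are mutual neighbors in the
#' similarity networks, while at cohesion 0 its genes scatter uniformly.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with elements \code{complexes}, \code{annotations},
#'   \code{dag}, \code{ppi}, \code{diseaseGenes} and \code{config}.
#' @examples
#' bundle <- generateSyntheticData(syntheticConfig(
#'   nGenes = 60, nComplexes = 12, nDiseases = 3, seed = 7))
#' bundle$complexes
#' @export
generateSyntheticData <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  .withSeed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$nGenes))
    clusterOf <- sort(rep_len(seq_len(config$nClusters), config$nGenes))
    pools <- split(genes, clusterOf)

    # complexes around anchor clusters
    sizes <- sample(seq(config$complexSizeRange[1],
                        config$complexSizeRange[2]),
                    config$nComplexes, replace = TRUE)
    anchors <- sample.int(config$nClusters, config$nComplexes,
                          replace = TRUE)
    mem <- lapply(seq_len(config$nComplexes), function(i)
      .sampleMembers(sizes[[i]], pools[[anchors[[i]]]], genes,
                     config$overlapRate))
    names(mem) <- sprintf("CPX%03d", seq_len(config$nComplexes))
    complexes <- ComplexSet(mem, sprintf("synthetic complex %d",
                                         seq_len(config$nComplexes)))

    # GO DAG and cluster-coherent annotations
    dag <- .makeDag(config$nGoTerms, config$dagDepth)
    nonRoot <- split(setdiff(goTerms(dag), goRoots(dag)),
                     dag@namespace[setdiff(goTerms(dag), goRoots(dag))])
    signatures <- lapply(seq_len(config$nClusters), function(k)
      lapply(nonRoot, function(terms)
        sample(terms, min(3L, length(terms)))))
    ann <- list()
    for (gi in seq_along(genes)) {
      k <- clusterOf[[gi]]
      for (sub in names(nonRoot)) {
        if (stats::runif(1) < config$annotationRate) {
          sig <- signatures[[k]][[sub]]
          take <- sample(sig, min(length(sig), sample(1:2, 1L)))
          ann[[length(ann) + 1L]] <- data.frame(
            gene_id = genes[[gi]], go_id = take, sub = sub,
            stringsAsFactors = FALSE)
        }
        if (stats::runif(1) < 0.2) {
          ann[[length(ann) + 1L]] <- data.frame(
            gene_id = genes[[gi]],
            go_id = sample(nonRoot[[sub]], 1L), sub = sub,
            stringsAsFactors = FALSE)
        }
      }
    }
    annotations <- unique(do.call(rbind, ann))

    # PPI: sparse background plus denser within-cluster wiring
    bg <- igraph::sample_gnp(config$nGenes, config$ppiEdgeProb)
    igraph::V(bg)$name <- genes
    extra <- do.call(rbind, lapply(pools, function(pool) {
      if (length(pool) < 2L) return(NULL)
      prs <- t(utils::combn(pool, 2L))
      prs[stats::runif(nrow(prs)) < min(0.2, 10 * config$ppiEdgeProb), ,
          drop = FALSE]
    }))
    ppi <- if (!is.null(extra) && nrow(extra)) {
      igraph::simplify(igraph::add_edges(bg, t(extra)))
    } else bg

    # diseases: cohesion-mixed gene draws
    dAnchors <- sample.int(config$nClusters, config$nDiseases,
                           replace = TRUE)
    diseaseGenes <- lapply(seq_len(config$nDiseases), function(d)
      .sampleMembers(config$genesPerDisease, pools[[dAnchors[[d]]]],
                     genes, config$cohesion))
    names(diseaseGenes) <- sprintf("MIM%04d", seq_len(config$nDiseases))

    list(complexes = complexes, annotations = annotations, dag = dag,
         ppi = ppi, diseaseGenes = diseaseGenes, config = config)
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the five input files in the package's TSV/OBO dialects —
#' complexes.tsv, disease_genes.tsv, ppi.tsv, gene2go.tsv, go.obo — plus a
#' manifest.json recording the generator settings and seed. Reading the
#' files back reproduces the in-memory bundle.
#'
#' @param bundle as returned by [generateSyntheticData()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
writeFixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("complexes.tsv", "disease_genes.tsv",
                            "ppi.tsv", "gene2go.tsv", "go.obo",
                            "manifest.json"))
  names(paths) <- c("complexes", "diseaseGenes", "ppi", "gene2go", "obo",
                    "manifest")
  mem <- members(bundle$complexes)
  writeLines(c("complex_id\tname\tmembers",
               sprintf("%s\t%s\t%s", names(mem),
                       complexNames(bundle$complexes),
                       vapply(mem, paste, character(1), collapse = ";"))),
             paths[["complexes"]])
  dg <- bundle$diseaseGenes
  writeLines(c("disease_id\tgene_id",
               sprintf("%s\t%s", rep(names(dg), lengths(dg)),
                       unlist(dg, use.names = FALSE))),
             paths[["diseaseGenes"]])
  el <- igraph::as_edgelist(bundle$ppi)
  writeLines(c("gene_a\tgene_b",
               if (nrow(el)) sprintf("%s\t%s", el[, 1], el[, 2])),
             paths[["ppi"]])
  sub2cat <- c(BP = "Process", CC = "Component", MF = "Function")
  a <- bundle$annotations
  writeLines(c("gene_id\tgo_id\tcategory",
               sprintf("%s\t%s\t%s", a$gene_id, a$go_id, sub2cat[a$sub])),
             paths[["gene2go"]])
  .writeObo(bundle$dag, paths[["obo"]])
  jsonlite::write_json(
    list(generator = "complexRank::generateSyntheticData",
         config = unclass(bundle$config)),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.writeObo <- function(dag, path) {
  tag2ns <- c(BP = "biological_process", CC = "cellular_component",
              MF = "molecular_function")
  lines <- c("format-version: 1.2", "ontology: synthetic-go", "")
  for (t in goTerms(dag)) {
    ns <- dag@namespace[[t]]
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: synthetic term ", t),
               if (!is.null(ns) && !is.na(ns))
                 paste0("namespace: ", tag2ns[[ns]]),
               paste0("is_a: ", dag@parents[[t]]), "")
  }
  writeLines(lines, path)
}

#' Read a fixture directory back into a bundle
#'
#' Inverse of [writeFixture()]: reads the five files and returns the same
#' structure as [generateSyntheticData()] (minus the config, which is only
#' in the manifest).
#'
#' @param dir directory written by [writeFixture()].
#' @return list with \code{complexes}, \code{annotations}, \code{dag},
#'   \code{ppi}, \code{diseaseGenes}.
#' @export
readFixture <- function(dir) {
  list(complexes = readComplexes(file.path(dir, "complexes.tsv")),
       annotations = readGene2go(file.path(dir, "gene2go.tsv")),
       dag = readObo(file.path(dir, "go.obo")),
       ppi = readPpi(file.path(dir, "ppi.tsv")),
       diseaseGenes = readDiseaseGenes(file.path(dir, "disease_genes.tsv")))
}
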