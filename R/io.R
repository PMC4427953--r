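# Readers and writers for the five external table dialects, plus derivation
# of disease -> complex seed profiles from disease -> gene associations.
#
# All files are plain TSV with a single header line. Gene, complex and
# disease identifiers are opaque, case-sensitive strings.

.readTsv <- function(path, ncol, what) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    stop(sprintf("%s: empty file '%s'", what, path))
  lines <- lines[nzchar(lines)]
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ncol)
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d of '%s' (expected %d fields)",
                 what, bad[1L] + 1L, path, ncol))
  parts
}

#' Read a protein-complex membership table
#'
#' Expects a CORUM-style TSV with a header line and rows
#' \code{complex_id<TAB>name<TAB>member1;member2;...}. Duplicate member
#' tokens within one complex are collapsed; an empty member field or a
#' duplicated complex id is an error.
#'
#' @param path path to the TSV file.
#' @return A [ComplexSet-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("complex_id\tname\tmembers",
#'              "10\t13S condensin\tA;B;C;D;E"), f)
#' readComplexes(f)
#' @export
readComplexes <- function(path) {
  parts <- .readTsv(path, 3L, "complex table")
  ids <- vapply(parts, `[[`, character(1), 1L)
  nms <- vapply(parts, `[[`, character(1), 2L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate complex id(s): ", paste(unique(dup), collapse = ", "))
  mem <- lapply(seq_along(parts), function(i) {
    toks <- strsplit(parts[[i]][3L], ";", fixed = TRUE)[[1L]]
    toks <- unique(toks[nzchar(toks)])
    if (length(toks) == 0L)
      stop(sprintf("complex table: empty member list at line %d of '%s'",
                   i + 1L, path))
    toks
  })
  names(mem) <- ids
  ComplexSet(mem, nms)
}

#' Read a disease-phenotype to gene association table
#'
#' TSV dialect: header line, then one \code{disease_id<TAB>gene_id} pair per
#' row.
#'
#' @param path path to the TSV file.
#' @return named list mapping disease id to the character vector of its
#'   associated genes (each non-empty, duplicates removed).
#' @export
readDiseaseGenes <- function(path) {
  parts <- .readTsv(path, 2L, "disease-gene table")
  d <- vapply(parts, `[[`, character(1), 1L)
  g <- vapply(parts, `[[`, character(1), 2L)
  lapply(split(g, d), unique)
}

#' Read a protein-protein interaction edge list
#'
#' TSV dialect: header line, then one \code{gene_a<TAB>gene_b} pair per row.
#' The graph is undirected: a pair listed in both orientations becomes a
#' single edge; self-loops are dropped.
#'
#' @param path path to the TSV file.
#' @return an undirected, simplified \code{igraph} graph over gene ids.
#' @export
readPpi <- function(path) {
  parts <- .readTsv(path, 2L, "PPI table")
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a gene-to-GO annotation table
#'
#' TSV dialect: header line, then rows
#' \code{gene_id<TAB>go_id<TAB>category} where category is one of
#' \code{Process}, \code{Component}, \code{Function} (NCBI gene2go style),
#' mapped to the sub-ontology tags BP, CC, MF respectively. Already-tagged
#' BP/CC/MF values are accepted as-is.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{gene_id}, \code{go_id}, \code{sub}
#'   (one of BP/CC/MF), duplicates removed.
#' @export
readGene2go <- function(path) {
  parts <- .readTsv(path, 3L, "gene2go table")
  cat2sub <- c(Process = "BP", Component = "CC", Function = "MF",
               BP = "BP", CC = "CC", MF = "MF")
  categ <- vapply(parts, `[[`, character(1), 3L)
  bad <- which(!categ %in% names(cat2sub))
  if (length(bad))
    stop(sprintf("gene2go table: unknown category '%s' at line %d of '%s'",
                 categ[bad[1L]], bad[1L] + 1L, path))
  out <- data.frame(
    gene_id = vapply(parts, `[[`, character(1), 1L),
    go_id = vapply(parts, `[[`, character(1), 2L),
    sub = unname(cat2sub[categ]),
    stringsAsFactors = FALSE)
  unique(out)
}

#' Write / read a weighted complex network
#'
#' TSV dialect: header line \code{complex_a<TAB>complex_b<TAB>weight}; each
#' undirected edge written once with the lexicographically smaller id first
#' and the weight printed with 6 decimals, so write-then-read is the
#' identity up to 1e-6 in the weights. Isolated nodes are not represented
#' in the file and are therefore not round-tripped.
#'
#' @param net a [WeightedNetwork-class].
#' @param path output (input) path.
#' @return \code{writeNetwork} invisibly returns \code{path};
#'   \code{readNetwork} returns a [WeightedNetwork-class].
#' @export
writeNetwork <- function(net, path) {
  e <- edges(net)
  lines <- c("complex_a\tcomplex_b\tweight",
             if (nrow(e)) sprintf("%s\t%s\t%.6f", e$from, e$to, e$weight))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  parts <- .readTsv(path, 3L, "network table")
  if (length(parts) == 0L)
    return(WeightedNetwork(data.frame(from = character(), to = character(),
                                      weight = numeric())))
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(w))
  if (length(bad))
    stop(sprintf("network table: non-numeric weight at line %d of '%s'",
                 bad[1L] + 1L, path))
  WeightedNetwork(data.frame(
    from = vapply(parts, `[[`, character(1), 1L),
    to = vapply(parts, `[[`, character(1), 2L),
    weight = w, stringsAsFactors = FALSE))
}

#' Derive disease -> complex seed profiles
#'
#' A complex is associated with a disease phenotype when at least one of its
#' subunits is one of the disease's genes. Diseases whose gene set hits no
#' complex are dropped (with a warning), mirroring the fact that only part
#' of a phenotype catalogue maps onto a complex catalogue.
#'
#' @param diseaseGenes named list: disease id -> character vector of genes
#'   (as from [readDiseaseGenes()]).
#' @param complexes a [ComplexSet-class].
#' @return named list: disease id -> character vector of seed complex ids.
#' @examples
#' cs <- ComplexSet(list(c1 = c("A", "B"), c2 = "C"))
#' deriveDiseaseComplexes(list(d1 = c("A", "C")), cs)
#' @export
deriveDiseaseComplexes <- function(diseaseGenes, complexes) {
  mem <- members(complexes)
  gene2cx <- split(
    rep(names(mem), lengths(mem)),
    unlist(mem, use.names = FALSE))
  profiles <- lapply(diseaseGenes, function(genes) {
    sort(unique(unlist(gene2cx[intersect(genes, names(gene2cx))],
                       use.names = FALSE)))
  })
  empty <- lengths(profiles) == 0L
  if (any(empty))
    warning(sprintf("%d disease(s) map to no complex and were dropped",
                    sum(empty)))
  profiles[!empty]
}

#' Keep only diseases with at least k seed complexes
#'
#' Leave-one-out validation needs at least two known associations per
#' disease, so evaluation typically uses \code{k = 2}.
#'
#' @param profiles named list: disease id -> seed complex ids.
#' @param k minimum number of seed complexes (>= 1).
#' @return the filtered named list.
#' @export
filterDiseasesMinSeeds <- function(profiles, k) {
  stopifnot(k >= 1)
  profiles[lengths(profiles) >= k]
}
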