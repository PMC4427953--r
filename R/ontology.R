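# GO DAG parsing and per-complex annotation closures.
#
# The closure of a complex is the union over its subunits of each subunit's
# direct GO terms plus all their ancestors along is_a / part_of edges,
# excluding the three sub-ontology roots.

.NS2TAG <- c(biological_process = "BP", cellular_component = "CC",
             molecular_function = "MF")
.CANONICAL_ROOTS <- c(BP = "GO:0008150", CC = "GO:0005575",
                      MF = "GO:0003674")

#' Read a GO ontology in OBO format
#'
#' A minimal OBO reader covering what the annotation closure needs:
#' \code{[Term]} stanzas with \code{id}, \code{name}, \code{namespace},
#' \code{is_a} and \code{relationship: part_of} lines. Obsolete terms are
#' skipped, and so are parent links pointing at skipped or unknown terms.
#' Relationship types other than \code{part_of} are ignored.
#'
#' @param path path to the .obo file.
#' @return a [GoDag-class]. Roots are the canonical ids (GO:0008150,
#'   GO:0005575, GO:0003674) when present, otherwise the parentless term of
#'   each sub-ontology.
#' @export
readObo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in '", path, "'")
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); ns <- character(); parents <- list()
  for (s in seq_along(starts)) {
    block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    getv <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      sub(paste0("^", key, ": "), "", v)
    }
    if (length(getv("is_obsolete")) && any(getv("is_obsolete") == "true"))
      next
    id <- getv("id")
    if (length(id) != 1L) next
    isa <- sub(" !.*$", "", getv("is_a"))
    rel <- getv("relationship")
    partof <- sub(" !.*$", "", sub("^part_of ", "",
                                   rel[startsWith(rel, "part_of ")]))
    nsv <- getv("namespace")
    ids <- c(ids, id)
    ns <- c(ns, if (length(nsv)) nsv[1L] else NA_character_)
    parents[[id]] <- unique(c(isa, partof))
  }
  names(ns) <- ids
  # drop parent links to obsolete/unknown terms
  parents <- lapply(parents, function(p) p[p %in% ids])
  tag <- unname(.NS2TAG[ns])
  names(tag) <- ids
  roots <- character()
  for (t in c("BP", "CC", "MF")) {
    cand <- ids[!is.na(tag) & tag == t & lengths(parents[ids]) == 0L]
    if (length(cand) == 0L) next
    roots[[t]] <- if (.CANONICAL_ROOTS[[t]] %in% cand)
      .CANONICAL_ROOTS[[t]] else cand[[1L]]
  }
  GoDag(parents, roots, namespace = tag[!is.na(tag)])
}

#' Ancestors of a GO term
#'
#' Transitive closure over parent (is_a / part_of) edges, excluding the term
#' itself and the sub-ontology roots. A term missing from the DAG (an
#' annotation snapshot newer than the ontology snapshot) yields an empty set
#' with a warning.
#'
#' @param dag a [GoDag-class].
#' @param term a single GO term id.
#' @return character vector of ancestor term ids (possibly empty).
#' @examples
#' dag <- GoDag(list(r = character(), a = "r", b = "a"), c(BP = "r"))
#' goAncestors(dag, "b")  # "a" only: the root is excluded
#' @export
goAncestors <- function(dag, term) {
  stopifnot(length(term) == 1L)
  if (!term %in% dag@terms) {
    warning("term not in DAG: ", term)
    return(character())
  }
  out <- .closureUp(dag, term)
  setdiff(out, c(term, unname(dag@roots)))
}

# all terms reachable upward from `term`, including `term`, no root filter
.closureUp <- function(dag, term, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[term]])) return(cache[[term]])
  seen <- character(); frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(dag@parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  seen <- unique(seen)
  if (!is.null(cache)) cache[[term]] <- seen
  seen
}

#' GO annotation closure of a protein complex
#'
#' Union over all complex subunits of (direct annotating terms in the given
#' sub-ontology, plus all their ancestors), with the sub-ontology roots
#' removed. Subunits with no annotation contribute nothing. A term present
#' in the annotation table but absent from the DAG contributes itself (with
#' a warning) but no ancestors.
#'
#' @param complexMembers character vector of gene ids (one complex's
#'   subunits).
#' @param annotations data.frame as from [readGene2go()] (columns
#'   \code{gene_id}, \code{go_id}, \code{sub}).
#' @param dag a [GoDag-class].
#' @param sub sub-ontology tag, one of \code{"BP"}, \code{"CC"}, \code{"MF"}.
#' @return character vector: the closed term set (roots excluded).
#' @export
complexGoProfile <- function(complexMembers, annotations, dag,
                             sub = c("BP", "CC", "MF")) {
  sub <- match.arg(sub)
  direct <- unique(annotations$go_id[
    annotations$sub == sub & annotations$gene_id %in% complexMembers])
  .profileFromDirect(direct, dag)
}

.profileFromDirect <- function(direct, dag, cache = NULL) {
  if (length(direct) == 0L) return(character())
  known <- direct[direct %in% dag@terms]
  unknown <- setdiff(direct, known)
  if (length(unknown))
    warning("annotation term(s) not in DAG: ",
            paste(utils::head(unknown, 3), collapse = ", "))
  closed <- unique(c(unknown, unlist(
    lapply(known, .closureUp, dag = dag, cache = cache),
    use.names = FALSE)))
  setdiff(closed, unname(dag@roots))
}

#' GO annotation closures for every complex in a set
#'
#' Vectorised companion to [complexGoProfile()] sharing one ancestor cache
#' across complexes.
#'
#' @param complexes a [ComplexSet-class].
#' @inheritParams complexGoProfile
#' @return named list: complex id -> closed term set (possibly empty).
#' @export
complexGoProfiles <- function(complexes, annotations, dag,
                              sub = c("BP", "CC", "MF")) {
  sub <- match.arg(sub)
  ann <- annotations[annotations$sub == sub, , drop = FALSE]
  gene2terms <- split(ann$go_id, ann$gene_id)
  cache <- new.env(parent = emptyenv())
  lapply(members(complexes), function(mem) {
    direct <- unique(unlist(gene2terms[intersect(mem, names(gene2terms))],
                            use.names = FALSE))
    .profileFromDirect(direct, dag, cache = cache)
  })
}
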