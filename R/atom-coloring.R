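#' @include molfile-io.R
NULL

## Per-atom eccentricity in bonds (max finite shortest-path distance within
## the atom's connected component). Computed with igraph.
.eccentricities <- function(graph) {
  n <- atomCount(graph)
  if (n == 1L) return(0L)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  b <- bonds(graph)
  if (nrow(b) > 0L)
    g <- igraph::add_edges(g, as.vector(t(b[, 1:2, drop = FALSE])))
  d <- igraph::distances(g)
  as.integer(apply(d, 1L, function(r) max(r[is.finite(r)])))
}

#' Atom-coloring featurization of a molecular graph
#'
#' Assigns every atom a canonical color identifier at each radius
#' r = 0, 1, ..., ecc(atom), where ecc(atom) is the atom's eccentricity in
#' bonds (the radius at which its bonded neighborhood stops growing; the
#' maximum over atoms is the graph diameter). The radius-0 color is the
#' element symbol; the radius-r color is
#' `element + "(" + sorted "order:neighborColor(r-1)" list + ")"`, i.e.
#' iterative neighborhood expansion with lexicographically sorted sub-colors,
#' which makes the identifier invariant under any re-ordering of atom
#' indices. Colors are counted across all atoms and all radii.
#'
#' @param graph A valid [MolecularGraph-class].
#' @return A [CountVector-class] of positive integer color counts, carrying
#'   the graph's bond count. The radius-0 colors sum to the non-hydrogen
#'   atom count.
#' @examples
#' eth <- MolecularGraph("ethanol", c("C", "C", "O"),
#'                       rbind(c(1, 2, 1), c(2, 3, 1)))
#' colorCounts(colorAtoms(eth))
#' @export
colorAtoms <- function(graph) {
  stopifnot(methods::is(graph, "MolecularGraph"))
  methods::validObject(graph)
  n <- atomCount(graph)
  el <- atoms(graph)
  b <- bonds(graph)
  ## adjacency: per atom, neighbor indices and the connecting bond order
  nbrIdx <- vector("list", n)
  nbrOrd <- vector("list", n)
  if (nrow(b) > 0L) {
    ends <- c(b[, 1L], b[, 2L])
    other <- c(b[, 2L], b[, 1L])
    ords <- c(b[, 3L], b[, 3L])
    o <- order(ends)
    sp <- split(seq_along(ends)[o], ends[o])
    for (k in names(sp)) {
      i <- as.integer(k)
      nbrIdx[[i]] <- other[sp[[k]]]
      nbrOrd[[i]] <- ords[sp[[k]]]
    }
  }
  ecc <- .eccentricities(graph)
  prev <- el
  emissions <- el
  for (r in seq_len(max(ecc))) {
    cur <- vapply(seq_len(n), function(i) {
      if (is.null(nbrIdx[[i]])) return(prev[i])   # isolated atom: stable
      sub <- paste0(nbrOrd[[i]], ":", prev[nbrIdx[[i]]])
      paste0(el[i], "(", paste(.radixSort(sub), collapse = ","), ")")
    }, character(1))
    emissions <- c(emissions, cur[ecc >= r])
    prev <- cur
  }
  tab <- table(emissions)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  CountVector(metaboliteId(graph), counts, bondCount(graph))
}

#' Build the atom-color vocabulary of a corpus
#'
#' Every color occurring in at least one entity gets a column; ordering is
#' deterministic (lexicographic in C collation), so the resulting feature
#' index is reproducible across runs and platforms. No minimum-frequency
#' filter is applied.
#'
#' @param corpus Non-empty list of [CountVector-class] objects.
#' @return Character vector of color identifiers in column order.
#' @export
buildVocabulary <- function(corpus) {
  if (length(corpus) == 0L)
    .stopf("metpairs_feature_error",
           "cannot build a vocabulary from an empty corpus")
  .radixSort(unique(unlist(lapply(corpus, function(cv)
    names(colorCounts(cv))), use.names = FALSE)))
}

#' Assemble count vectors into a sparse feature matrix
#'
#' @param corpus List of [CountVector-class] objects (rows, in list order).
#' @param vocabulary Column order; defaults to [buildVocabulary()] of the
#'   corpus. Colors absent from the vocabulary are ignored, so a matrix for
#'   new entities can be laid out against a previously fixed vocabulary.
#' @return A `dgCMatrix` with entity ids as row names and color identifiers
#'   as column names.
#' @export
featureMatrix <- function(corpus, vocabulary = NULL) {
  vocabulary <- vocabulary %||% buildVocabulary(corpus)
  ids <- vapply(corpus, entityId, character(1))
  if (anyDuplicated(ids))
    .stopf("metpairs_feature_error", "duplicated entity ids: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  triplets <- lapply(seq_along(corpus), function(k) {
    cts <- colorCounts(corpus[[k]])
    j <- match(names(cts), vocabulary)
    keep <- !is.na(j)
    cbind(i = rep.int(k, sum(keep)), j = j[keep], x = unname(cts[keep]))
  })
  tr <- do.call(rbind, triplets)
  Matrix::sparseMatrix(i = tr[, 1L], j = tr[, 2L], x = tr[, 3L],
                       dims = c(length(corpus), length(vocabulary)),
                       dimnames = list(ids, vocabulary))
}
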