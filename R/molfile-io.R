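#' @include AllClasses.R
NULL

.parseError <- function(id, fmt, ...) {
  .stopf("metpairs_parse_error", paste0("metabolite '%s': ", fmt), id, ...)
}

.molfileInt <- function(line, from, to, id, what) {
  v <- suppressWarnings(as.integer(trimws(substr(line, from, to))))
  if (is.na(v)) .parseError(id, "cannot read %s from line '%s'", what, line)
  v
}

#' Parse an MDL V2000 molfile into a hydrogen-free molecular graph
#'
#' Reads the counts line, atom block and bond block of a V2000 connection
#' table, removes all explicit hydrogens together with their incident bonds,
#' and re-indexes the remaining atoms contiguously. Bond orders are
#' preserved (4 = aromatic, kept as its own order). Charges, isotopes and
#' stereo flags are ignored; coordinates are discarded. V3000 input is
#' rejected as unsupported.
#'
#' @param text Molfile content: a single string (with newlines) or a
#'   character vector of lines.
#' @param metaboliteId Identifier for the molecule; defaults to the (trimmed)
#'   first header line, or `"molfile"` when that is empty.
#' @return A [MolecularGraph-class].
#' @examples
#' mol <- parseMolfile(c("ethanol", "", "",
#'   "  9  8  0  0  0  0  0  0  0  0999 V2000",
#'   rep("    0.0000    0.0000    0.0000 C   0  0  0  0  0  0", 2),
#'   "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0",
#'   rep("    0.0000    0.0000    0.0000 H   0  0  0  0  0  0", 6),
#'   "  1  2  1  0", "  2  3  1  0", "  1  4  1  0", "  1  5  1  0",
#'   "  1  6  1  0", "  2  7  1  0", "  2  8  1  0", "  3  9  1  0",
#'   "M  END"))
#' atomCount(mol)  # 3: the hydrogens are stripped
#' @export
parseMolfile <- function(text, metaboliteId = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  id <- metaboliteId %||% {
    h <- if (length(lines)) trimws(lines[1]) else ""
    if (nzchar(h)) h else "molfile"
  }
  if (length(lines) < 4L)
    .parseError(id, "molfile has fewer than 4 lines")
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE))
    .parseError(id, "V3000 molfiles are not supported (V2000 only)")
  na <- .molfileInt(counts, 1, 3, id, "atom count")
  nb <- .molfileInt(counts, 4, 6, id, "bond count")
  if (na < 1L) .parseError(id, "counts line declares %d atoms", na)
  if (length(lines) < 4L + na + nb)
    .parseError(id, "molfile truncated: %d atoms + %d bonds declared", na, nb)

  atomLines <- lines[5:(4L + na)]
  elements <- trimws(substr(atomLines, 32, 34))
  if (any(!nzchar(elements)))
    .parseError(id, "atom line without element symbol")

  bond <- matrix(integer(), ncol = 3L)
  if (nb > 0L) {
    bondLines <- lines[(5L + na):(4L + na + nb)]
    bond <- cbind(
      vapply(bondLines, .molfileInt, integer(1), from = 1, to = 3,
             id = id, what = "bond atom a", USE.NAMES = FALSE),
      vapply(bondLines, .molfileInt, integer(1), from = 4, to = 6,
             id = id, what = "bond atom b", USE.NAMES = FALSE),
      vapply(bondLines, .molfileInt, integer(1), from = 7, to = 9,
             id = id, what = "bond order", USE.NAMES = FALSE))
    if (any(bond[, 1:2] < 1L) || any(bond[, 1:2] > na))
      .parseError(id, "bond references atom index out of range 1..%d", na)
    if (any(bond[, 1L] == bond[, 2L]))
      .parseError(id, "bond with identical endpoints")
    key <- paste(pmin(bond[, 1L], bond[, 2L]), pmax(bond[, 1L], bond[, 2L]))
    if (anyDuplicated(key))
      .parseError(id, "duplicate bond between the same atom pair")
    if (!all(bond[, 3L] %in% 1:4))
      .parseError(id, "bond order outside {1,2,3,4}")
  }

  keep <- elements != "H"
  if (!any(keep))
    .parseError(id, "no non-hydrogen atoms remain after hydrogen stripping")
  newIdx <- cumsum(keep)           # old index -> new index (H rows unused)
  if (nrow(bond) > 0L) {
    hb <- keep[bond[, 1L]] & keep[bond[, 2L]]
    bond <- bond[hb, , drop = FALSE]
    if (nrow(bond) > 0L) {
      bond[, 1L] <- newIdx[bond[, 1L]]
      bond[, 2L] <- newIdx[bond[, 2L]]
    }
  }
  MolecularGraph(id, elements[keep], bond)
}

#' Read a directory of molfiles
#'
#' Parses every `*.mol` file in `dir` (the file base name becomes the
#' metabolite id). Entries that fail to parse — e.g. V3000 files or
#' molecules whose only atoms are hydrogens — are skipped with a warning
#' naming the offending file, mirroring the handling of database entries
#' with polymer/R-group markers.
#'
#' @param dir Directory path.
#' @param pattern File name regular expression (default `"\\.mol$"`).
#' @return Named list of [MolecularGraph-class] objects.
#' @export
readMolfileDir <- function(dir, pattern = "\\.mol$") {
  if (!dir.exists(dir))
    .stopf("metpairs_io_error", "molfile directory '%s' does not exist", dir)
  paths <- .radixSort(list.files(dir, pattern = pattern, full.names = TRUE))
  graphs <- list()
  for (p in paths) {
    id <- sub(pattern, "", basename(p))
    g <- tryCatch(parseMolfile(readLines(p, warn = FALSE), id),
                  metpairs_parse_error = function(e) {
                    .warnf("skipping '%s': %s", basename(p),
                           conditionMessage(e))
                    NULL
                  })
    if (!is.null(g)) graphs[[id]] <- g
  }
  graphs
}

#' Serialize a molecular graph as a V2000 molfile
#'
#' Writes a minimal valid V2000 connection table (all coordinates zero) that
#' round-trips through [parseMolfile()]. Used by the synthetic-corpus
#' generator; no explicit hydrogens are emitted.
#'
#' @param graph A [MolecularGraph-class].
#' @param path Optional file path; when `NULL` the text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the molfile text as
#'   a character vector of lines.
#' @export
writeMolfile <- function(graph, path = NULL) {
  stopifnot(methods::is(graph, "MolecularGraph"))
  b <- bonds(graph)
  lines <- c(
    metaboliteId(graph),
    "  metpairs",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            atomCount(graph), bondCount(graph)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, atoms(graph)),
    if (nrow(b)) sprintf("%3d%3d%3d  0", b[, 1L], b[, 2L], b[, 3L]),
    "M  END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Persist molecular graphs as canonical TSV tables
#'
#' The internal persisted graph format: one atoms table
#' (`metabolite_id`, `atom_index`, `element`) and one bonds table
#' (`metabolite_id`, `a`, `b`, `order`). [readGraphTables()] reproduces the
#' identical graphs (round-trip property).
#'
#' @param graphs List of [MolecularGraph-class] objects.
#' @param atomsFile,bondsFile Output TSV paths.
#' @return Invisibly `NULL`.
#' @export
writeGraphTables <- function(graphs, atomsFile, bondsFile) {
  at <- do.call(rbind, lapply(graphs, function(g)
    data.frame(metabolite_id = metaboliteId(g),
               atom_index = seq_len(atomCount(g)),
               element = atoms(g))))
  bd <- do.call(rbind, lapply(graphs, function(g) {
    b <- bonds(g)
    if (nrow(b) == 0L) return(NULL)
    data.frame(metabolite_id = metaboliteId(g),
               a = b[, 1L], b = b[, 2L], order = b[, 3L])
  }))
  if (is.null(bd))
    bd <- data.frame(metabolite_id = character(), a = integer(),
                     b = integer(), order = integer())
  .writeTSV(at, atomsFile)
  .writeTSV(bd, bondsFile)
  invisible(NULL)
}

#' @rdname writeGraphTables
#' @return For `readGraphTables()`, a named list of
#'   [MolecularGraph-class] objects.
#' @export
readGraphTables <- function(atomsFile, bondsFile) {
  at <- .readTSV(atomsFile)
  bd <- .readTSV(bondsFile)
  ids <- unique(at$metabolite_id)
  out <- lapply(ids, function(id) {
    a <- at[at$metabolite_id == id, , drop = FALSE]
    a <- a[order(a$atom_index), , drop = FALSE]
    b <- bd[bd$metabolite_id == id, c("a", "b", "order"), drop = FALSE]
    MolecularGraph(id, a$element, as.matrix(b))
  })
  names(out) <- ids
  out
}
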