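#' @include atom-coloring.R
NULL

#' Pathway definitions from a membership table
#'
#' Computes, per pathway, the two size metrics used throughout the
#' analyses: `size_compounds`, the number of member metabolites, and
#' `size_atoms`, the sum of non-hydrogen atoms across all member
#' metabolites.
#'
#' @param membership `data.frame` with columns `pathway_id`, `level`
#'   (`"L2"` or `"L3"`) and `metabolite_id`; one row per membership.
#' @param graphs Named list of [MolecularGraph-class] objects covering every
#'   member metabolite (needed for the atom-based size metric).
#' @return `data.frame` with columns `pathway_id`, `level`,
#'   `size_compounds`, `size_atoms` and a list column `members`.
#' @export
pathwayDefinitions <- function(membership, graphs) {
  need <- c("pathway_id", "level", "metabolite_id")
  if (!all(need %in% names(membership)))
    .stopf("metpairs_dataset_error",
           "membership table must have columns %s",
           paste(need, collapse = ", "))
  if (!all(membership$level %in% c("L2", "L3")))
    .stopf("metpairs_dataset_error",
           "hierarchy level must be 'L2' or 'L3'")
  if (anyDuplicated(membership[c("pathway_id", "metabolite_id")]))
    .stopf("metpairs_dataset_error",
           "duplicated (pathway, metabolite) membership rows")
  missing <- setdiff(membership$metabolite_id, names(graphs))
  if (length(missing))
    .stopf("metpairs_dataset_error",
           "no molecular graph for member metabolite(s): %s",
           paste(utils::head(missing, 5), collapse = ", "))
  natoms <- vapply(graphs, atomCount, integer(1))
  sp <- split(membership$metabolite_id, membership$pathway_id)
  lvl <- membership$level[!duplicated(membership$pathway_id)]
  names(lvl) <- membership$pathway_id[!duplicated(membership$pathway_id)]
  ids <- .radixSort(names(sp))
  out <- data.frame(
    pathway_id = ids,
    level = unname(lvl[ids]),
    size_compounds = vapply(sp[ids], length, integer(1)),
    size_atoms = vapply(sp[ids], function(m)
      sum(natoms[m]), integer(1)),
    row.names = NULL)
  out$members <- unname(sp[ids])
  out
}

#' Pathway chemical-structure features
#'
#' A pathway's feature vector is the element-wise sum of the (raw, i.e.
#' un-normalized) count vectors of its member metabolites; its bond count is
#' the sum of member bond counts. Normalization is applied afterwards,
#' entry-wise, with [softmaxByBondCount()]. Note that a positive pair's
#' query metabolite is itself among the pathway's members (no exclusion
#' rule is applied), a documented source of optimistic bias.
#'
#' @param pathways Pathway table from [pathwayDefinitions()].
#' @param corpus Named list of [CountVector-class] objects, one per
#'   metabolite (raw counts from [colorAtoms()]).
#' @return Named list of [CountVector-class] objects, one per pathway.
#' @export
buildPathwayFeatures <- function(pathways, corpus) {
  out <- vector("list", nrow(pathways))
  names(out) <- pathways$pathway_id
  for (k in seq_len(nrow(pathways))) {
    pid <- pathways$pathway_id[k]
    members <- pathways$members[[k]]
    miss <- setdiff(members, names(corpus))
    if (length(miss))
      .stopf("metpairs_dataset_error",
             "pathway '%s': metabolite '%s' has no feature vector",
             pid, miss[1])
    acc <- numeric()
    bc <- 0L
    for (m in members) {
      cv <- corpus[[m]]
      if (isNormalized(cv))
        .stopf("metpairs_dataset_error",
               "pathway features must be built from raw counts ('%s' is normalized)",
               m)
      cts <- colorCounts(cv)
      hit <- match(names(cts), names(acc))
      old <- !is.na(hit)
      acc[hit[old]] <- acc[hit[old]] + cts[old]
      acc <- c(acc, cts[!old])
      bc <- bc + bondCount(cv)
    }
    out[[pid]] <- CountVector(pid, acc, bc)
  }
  out
}

#' Softmax-by-bond-count entry-wise normalization
#'
#' Divides each stored count by the entity's bond count B and applies a
#' softmax over the entity's non-zero colors only (sparse softmax):
#' `out_i = exp(c_i / B) / sum_j exp(c_j / B)`. Zero counts stay zero and
#' the non-zero outputs sum to 1. Entities with zero bonds (single-atom
#' molecules) use B = 1.
#'
#' @param v A raw-count [CountVector-class].
#' @return A [CountVector-class] with `isNormalized(v)` `TRUE`.
#' @examples
#' cv <- CountVector("x", c(a = 2, b = 1), bondCount = 1)
#' colorCounts(softmaxByBondCount(cv))  # exp(2)/(exp(2)+exp(1)), ...
#' @export
softmaxByBondCount <- function(v) {
  stopifnot(methods::is(v, "CountVector"))
  cts <- colorCounts(v)
  if (length(cts) == 0L || sum(cts) == 0)
    .stopf("metpairs_dataset_error",
           "cannot normalize an all-zero count vector ('%s')", entityId(v))
  B <- max(1L, bondCount(v))
  s <- cts / B
  e <- exp(s - max(s))                      # numerically stable softmax
  CountVector(entityId(v), e / sum(e), bondCount(v), normalized = TRUE)
}

#' Cross join metabolite and pathway feature vectors
#'
#' Builds the full Cartesian product: every metabolite paired with every
#' pathway, exactly once, for `|M| x |P|` entries. Each entry's feature
#' block concatenates the metabolite's and the pathway's normalized vectors
#' under disjoint column namespaces (`met::`, `pw::`), and its binary label
#' is 1 exactly when the metabolite is a member of the pathway. The cross
#' join is what turns a scarce per-pathway positive set into a large paired
#' training set for a single binary classifier.
#'
#' @param metMatrix Sparse metabolite feature matrix (rows named by
#'   metabolite id), e.g. from [featureMatrix()] of normalized vectors.
#' @param pwMatrix Sparse pathway feature matrix (rows named by pathway id).
#' @param membership Membership `data.frame` (`pathway_id`, `level`,
#'   `metabolite_id`).
#' @param pathwayInfo Pathway table from [pathwayDefinitions()] (sizes are
#'   carried into the dataset for the size analyses). Defaults to compound
#'   counts derived from `membership` with `size_atoms` unknown (`NA`).
#' @param provenance Optional list stored on the dataset.
#' @return A [PairedDataset-class]. Entries are metabolite-major: all
#'   pathways for the first metabolite, then the second, and so on.
#' @export
crossJoin <- function(metMatrix, pwMatrix, membership, pathwayInfo = NULL,
                      provenance = list()) {
  metIds <- unname(rownames(metMatrix))
  pwIds <- unname(rownames(pwMatrix))
  if (is.null(metIds) || anyDuplicated(metIds))
    .stopf("metpairs_dataset_error",
           "metabolite matrix must have unique row names")
  if (is.null(pwIds) || anyDuplicated(pwIds))
    .stopf("metpairs_dataset_error",
           "pathway matrix must have unique row names")
  M <- length(metIds)
  P <- length(pwIds)
  ii <- rep(seq_len(M), each = P)
  jj <- rep.int(seq_len(P), M)
  X <- cbind(metMatrix[ii, , drop = FALSE], pwMatrix[jj, , drop = FALSE])
  metNames <- paste0("met::", colnames(metMatrix))
  pwNames <- paste0("pw::", colnames(pwMatrix))
  dimnames(X) <- list(NULL, c(metNames, pwNames))
  memKey <- paste(membership$metabolite_id, membership$pathway_id,
                  sep = "\r")
  entryKey <- paste(metIds[ii], pwIds[jj], sep = "\r")
  labels <- as.integer(entryKey %in% memKey)
  lvl <- membership$level[match(pwIds, membership$pathway_id)]
  if (is.null(pathwayInfo)) {
    sizes <- table(membership$pathway_id)
    pathwayInfo <- data.frame(
      pathway_id = pwIds,
      level = lvl,
      size_compounds = as.integer(sizes[pwIds]),
      size_atoms = NA_integer_)
  } else {
    pathwayInfo <- pathwayInfo[match(pwIds, pathwayInfo$pathway_id),
                               c("pathway_id", "level", "size_compounds",
                                 "size_atoms")]
  }
  methods::new("PairedDataset",
               features = methods::as(X, "CsparseMatrix"),
               labels = labels,
               metaboliteIds = metIds[ii],
               pathwayIds = pwIds[jj],
               levels = pathwayInfo$level[jj],
               metFeatureNames = metNames,
               pwFeatureNames = pwNames,
               pathwayInfo = pathwayInfo,
               provenance = provenance)
}

## Fit per-column min/max over a row subset. Features are non-negative, so
## a column's min is 0 unless it is stored in every fitted row.
.minmaxFit <- function(X, rows) {
  Xs <- X[rows, , drop = FALSE]
  nz <- diff(Xs@p)
  mx <- .colMaxNZ(Xs)
  mn <- .colMinNZ(Xs)
  mx[nz == 0L] <- 0
  mn[nz < nrow(Xs)] <- pmin(mn[nz < nrow(Xs)], 0)
  mn[nz == 0L] <- 0
  list(min = mn, max = mx)
}

## Apply a min/max fit: x' = (x - min) / (max - min), constant columns -> 0,
## results clipped to [0, 1]. Implicit zeros map to 0 because min >= 0.
.minmaxApply <- function(X, fit) {
  rng <- fit$max - fit$min
  const <- rng <= 0
  rng[const] <- 1
  j <- rep(seq_len(ncol(X)), diff(X@p))
  x <- (X@x - fit$min[j]) / rng[j]
  x[const[j]] <- 0
  X@x <- pmin(pmax(x, 0), 1)
  Matrix::drop0(X)
}

#' Feature-wise min/max scaling
#'
#' Standard min/max scaling so that each feature value ranges between 0 and
#' 1. The column minima and maxima are computed over the `fitOn` entries
#' only (in cross-validation, the training split of each iteration, to
#' avoid leakage) and then applied to all entries: values outside the fit
#' range are clipped to \[0, 1\] and constant columns map to 0.
#'
#' @param dataset A [PairedDataset-class].
#' @param fitOn Entry indices the scaler is fit on (default: all entries,
#'   the global-fit variant).
#' @return The scaled [PairedDataset-class]; `provenance(x)$scaled` is set.
#' @export
minmaxScale <- function(dataset, fitOn = seq_len(nEntries(dataset))) {
  stopifnot(methods::is(dataset, "PairedDataset"))
  if (length(fitOn) == 0L)
    .stopf("metpairs_dataset_error", "fitOn must be non-empty")
  fit <- .minmaxFit(features(dataset), fitOn)
  prov <- provenance(dataset)
  prov$scaled <- TRUE
  prov$scaleFitEntries <- length(fitOn)
  methods::initialize(dataset,
                      features = .minmaxApply(features(dataset), fit),
                      provenance = prov)
}

#' @describeIn filterPathwaysBySize Restrict a cross-joined dataset to the
#'   pathways at or above the size threshold (all their entries, both
#'   labels, are retained).
#' @export
setMethod("filterPathwaysBySize", "PairedDataset",
          function(x, threshold, metric = c("compounds", "atoms")) {
  metric <- match.arg(metric)
  info <- pathwayInfo(x)
  sizes <- if (metric == "compounds") info$size_compounds else
    info$size_atoms
  keep <- info$pathway_id[sizes >= threshold]
  if (length(keep) == 0L)
    .stopf("metpairs_dataset_error",
           "threshold %s removes every pathway", format(threshold))
  x[pathwayIds(x) %in% keep]
})

#' @describeIn filterPathwaysBySize Filter a pathway table (rows with
#'   size below the threshold are dropped).
#' @export
setMethod("filterPathwaysBySize", "data.frame",
          function(x, threshold, metric = c("compounds", "atoms")) {
  metric <- match.arg(metric)
  sizes <- if (match.arg(metric) == "compounds") x$size_compounds else
    x$size_atoms
  out <- x[sizes >= threshold, , drop = FALSE]
  if (nrow(out) == 0L)
    .stopf("metpairs_dataset_error",
           "threshold %s removes every pathway", format(threshold))
  out
})

#' Persist / load a paired dataset
#'
#' Directory layout: `features.mtx` (MatrixMarket sparse), `columns.tsv`
#' (ordered feature names with their block), `entries.tsv` (per-entry
#' metabolite id, pathway id, level, label), `pathways.tsv` (pathway table)
#' and `provenance.json`.
#'
#' @param dataset A [PairedDataset-class].
#' @param dir Output (or input) directory.
#' @return `writePairedDataset()` returns `dir` invisibly;
#'   `readPairedDataset()` returns the reconstructed
#'   [PairedDataset-class].
#' @export
writePairedDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(features(dataset), file.path(dir, "features.mtx"))
  .writeTSV(data.frame(
    name = colnames(features(dataset)),
    block = rep(c("met", "pw"),
                c(length(metFeatureNames(dataset)),
                  length(pwFeatureNames(dataset))))),
    file.path(dir, "columns.tsv"))
  .writeTSV(data.frame(metabolite_id = metaboliteIds(dataset),
                       pathway_id = pathwayIds(dataset),
                       level = entryLevels(dataset),
                       label = entryLabels(dataset)),
            file.path(dir, "entries.tsv"))
  info <- pathwayInfo(dataset)
  .writeTSV(info[c("pathway_id", "level", "size_compounds", "size_atoms")],
            file.path(dir, "pathways.tsv"))
  .writeJSON(provenance(dataset), file.path(dir, "provenance.json"))
  invisible(dir)
}

#' @rdname writePairedDataset
#' @export
readPairedDataset <- function(dir) {
  X <- methods::as(Matrix::readMM(file.path(dir, "features.mtx")),
                   "CsparseMatrix")
  cols <- .readTSV(file.path(dir, "columns.tsv"))
  entries <- .readTSV(file.path(dir, "entries.tsv"))
  info <- .readTSV(file.path(dir, "pathways.tsv"))
  prov <- as.list(.readJSON(file.path(dir, "provenance.json")))
  colnames(X) <- cols$name
  methods::new("PairedDataset",
               features = X,
               labels = as.integer(entries$label),
               metaboliteIds = as.character(entries$metabolite_id),
               pathwayIds = as.character(entries$pathway_id),
               levels = as.character(entries$level),
               metFeatureNames = cols$name[cols$block == "met"],
               pwFeatureNames = cols$name[cols$block == "pw"],
               pathwayInfo = info,
               provenance = prov)
}

#' Build a paired dataset from molfiles and a membership table
#'
#' End-to-end dataset construction: parse molfiles, color atoms, build the
#' metabolite and pathway vocabularies, sum member counts into pathway
#' vectors, normalize everything entry-wise with softmax by bond count, and
#' cross join. Feature-wise min/max scaling is deliberately *not* applied
#' here: it is fit per cross-validation iteration on the training split
#' (see [runCV()]), or explicitly with [minmaxScale()].
#'
#' @param graphs Named list of [MolecularGraph-class] (e.g. from
#'   [readMolfileDir()]).
#' @param membership Membership `data.frame` (`pathway_id`, `level`,
#'   `metabolite_id`).
#' @param levels Hierarchy levels to keep (default both `"L2"` and `"L3"`).
#' @param allowMissing Drop membership rows whose metabolite has no graph
#'   (with a warning) instead of erroring.
#' @return A [PairedDataset-class] over all parsed metabolites and the
#'   selected pathways.
#' @export
buildPairedDataset <- function(graphs, membership,
                               levels = c("L2", "L3"),
                               allowMissing = FALSE) {
  membership <- membership[membership$level %in% levels, , drop = FALSE]
  if (nrow(membership) == 0L)
    .stopf("metpairs_dataset_error", "no membership rows at level(s) %s",
           paste(levels, collapse = ","))
  miss <- setdiff(membership$metabolite_id, names(graphs))
  if (length(miss)) {
    if (!allowMissing)
      .stopf("metpairs_dataset_error",
             "missing molfiles for metabolite(s): %s",
             paste(utils::head(miss, 10), collapse = ", "))
    .warnf("dropping %d membership rows without molfiles", length(miss))
    membership <- membership[!membership$metabolite_id %in% miss, ,
                             drop = FALSE]
  }
  corpus <- lapply(graphs, colorAtoms)
  info <- pathwayDefinitions(membership, graphs)
  pwRaw <- buildPathwayFeatures(info, corpus)
  metNorm <- lapply(corpus, softmaxByBondCount)
  pwNorm <- lapply(pwRaw, softmaxByBondCount)
  metMat <- featureMatrix(metNorm)
  pwMat <- featureMatrix(pwNorm)
  crossJoin(metMat, pwMat, membership, pathwayInfo = info,
            provenance = list(
              scaled = FALSE,
              levels = levels,
              nMetabolites = nrow(metMat),
              nPathways = nrow(pwMat)))
}
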