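#' @include AllGenerics.R
NULL

#' MolecularGraph: a hydrogen-free molecular graph
#'
#' Atoms are element-labeled nodes (explicit hydrogens are removed at parse
#' time) and bonds are typed edges with order 1, 2, 3 or 4 (aromatic, kept as
#' its own order without kekulization). Disconnected components (e.g. salts)
#' are retained as a single graph.
#'
#' @slot metaboliteId Single identifier string.
#' @slot atoms Character vector of element symbols, one per non-hydrogen atom.
#' @slot bonds Integer matrix with columns `a`, `b`, `order`; `a`/`b` are
#'   1-based atom indices.
#'
#' @seealso [parseMolfile()], [colorAtoms()]
#' @export
setClass("MolecularGraph",
         representation(metaboliteId = "character",
                        atoms = "character",
                        bonds = "matrix"))

setValidity("MolecularGraph", function(object) {
  msgs <- character()
  if (length(object@metaboliteId) != 1L || is.na(object@metaboliteId))
    msgs <- c(msgs, "metaboliteId must be a single string")
  if (length(object@atoms) < 1L)
    msgs <- c(msgs, "graph must contain at least one non-hydrogen atom")
  if (any(object@atoms == "H"))
    msgs <- c(msgs, "explicit hydrogens must be removed")
  b <- object@bonds
  if (!is.integer(b) || ncol(b) != 3L) {
    msgs <- c(msgs, "bonds must be an integer matrix with 3 columns")
  } else if (nrow(b) > 0L) {
    n <- length(object@atoms)
    if (any(b[, 1:2] < 1L) || any(b[, 1:2] > n))
      msgs <- c(msgs, "bond endpoint out of range")
    if (any(b[, 1L] == b[, 2L]))
      msgs <- c(msgs, "self-bond (a == b) not allowed")
    key <- paste(pmin(b[, 1L], b[, 2L]), pmax(b[, 1L], b[, 2L]))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate unordered bond pair")
    if (!all(b[, 3L] %in% 1:4))
      msgs <- c(msgs, "bond order must be in {1,2,3,4}")
  }
  if (length(msgs)) msgs else TRUE
})

MolecularGraph <- function(metaboliteId, atoms, bonds) {
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(), ncol = 3L)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 3L,
                    dimnames = NULL)
  }
  colnames(bonds) <- c("a", "b", "order")
  methods::new("MolecularGraph", metaboliteId = as.character(metaboliteId),
               atoms = as.character(atoms), bonds = bonds)
}

#' @rdname accessors
#' @export
setMethod("metaboliteId", "MolecularGraph", function(x) x@metaboliteId)
#' @rdname accessors
#' @export
setMethod("atoms", "MolecularGraph", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "MolecularGraph", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("atomCount", "MolecularGraph", function(x) length(x@atoms))
#' @rdname accessors
#' @export
setMethod("bondCount", "MolecularGraph", function(x) nrow(x@bonds))

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d non-H atoms, %d bonds\n",
              object@metaboliteId, atomCount(object), bondCount(object)))
  tab <- table(object@atoms)
  cat("  composition:",
      paste(sprintf("%s%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
})

#' CountVector: sparse atom-color counts for one entity
#'
#' The featurization of one metabolite (or of one pathway, as the sum over
#' its member metabolites): a sparse mapping from canonical atom-color
#' identifier to a positive value, plus the entity's bond count, which is
#' the divisor of the softmax-by-bond-count normalization.
#'
#' @slot id Entity identifier (metabolite or pathway id).
#' @slot counts Named numeric vector (names = color identifiers); raw counts
#'   are positive integers, normalized values lie in (0, 1].
#' @slot bondCount Non-negative integer.
#' @slot normalized Logical; `TRUE` after [softmaxByBondCount()].
#'
#' @seealso [colorAtoms()], [buildPathwayFeatures()], [softmaxByBondCount()]
#' @export
setClass("CountVector",
         representation(id = "character",
                        counts = "numeric",
                        bondCount = "integer",
                        normalized = "logical"))

setValidity("CountVector", function(object) {
  msgs <- character()
  if (length(object@id) != 1L)
    msgs <- c(msgs, "id must be a single string")
  if (length(object@counts) &&
      (is.null(names(object@counts)) || anyDuplicated(names(object@counts))))
    msgs <- c(msgs, "counts must have unique names (color identifiers)")
  if (any(object@counts <= 0))
    msgs <- c(msgs, "stored counts must be positive (sparse semantics)")
  if (length(object@bondCount) != 1L || object@bondCount < 0L)
    msgs <- c(msgs, "bondCount must be a single non-negative integer")
  if (length(msgs)) msgs else TRUE
})

CountVector <- function(id, counts, bondCount, normalized = FALSE) {
  if (length(counts))
    counts <- counts[order(names(counts), method = "radix")]
  else counts <- stats::setNames(numeric(), character())
  methods::new("CountVector", id = as.character(id),
               counts = counts, bondCount = as.integer(bondCount),
               normalized = normalized)
}

#' @rdname accessors
#' @export
setMethod("entityId", "CountVector", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("colorCounts", "CountVector", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("bondCount", "CountVector", function(x) x@bondCount)
#' @rdname accessors
#' @export
setMethod("isNormalized", "CountVector", function(x) x@normalized)

setMethod("show", "CountVector", function(object) {
  cat(sprintf("CountVector '%s': %d colors, bondCount %d%s\n",
              object@id, length(object@counts), object@bondCount,
              if (object@normalized) " (normalized)" else ""))
})

#' PairedDataset: cross-joined metabolite-pathway entries
#'
#' The full Cartesian product of a metabolite set and a pathway set. Each
#' entry pairs one metabolite's feature vector with one pathway's feature
#' vector under disjoint column namespaces (`met::`, `pw::`) and carries a
#' binary label that is 1 exactly when the metabolite is a member of the
#' pathway.
#'
#' @slot features Sparse `dgCMatrix`, entries in rows; non-negative values.
#' @slot labels Integer 0/1 vector, one per entry.
#' @slot metaboliteIds,pathwayIds,levels Character vectors, one per entry.
#' @slot metFeatureNames,pwFeatureNames Ordered column names of the two
#'   feature blocks.
#' @slot pathwayInfo `data.frame` with columns `pathway_id`, `level`,
#'   `size_compounds`, `size_atoms`, one row per pathway in the dataset.
#' @slot provenance List recording how the dataset was built (thresholds,
#'   scaling flag, seeds).
#'
#' @seealso [crossJoin()], [minmaxScale()], [filterPathwaysBySize()]
#' @export
setClass("PairedDataset",
         representation(features = "dgCMatrix",
                        labels = "integer",
                        metaboliteIds = "character",
                        pathwayIds = "character",
                        levels = "character",
                        metFeatureNames = "character",
                        pwFeatureNames = "character",
                        pathwayInfo = "data.frame",
                        provenance = "list"))

setValidity("PairedDataset", function(object) {
  msgs <- character()
  n <- nrow(object@features)
  if (length(object@labels) != n || length(object@metaboliteIds) != n ||
      length(object@pathwayIds) != n || length(object@levels) != n)
    msgs <- c(msgs, "per-entry slots must all have length nrow(features)")
  if (!all(object@labels %in% 0:1))
    msgs <- c(msgs, "labels must be 0/1")
  if (!identical(colnames(object@features),
                 c(object@metFeatureNames, object@pwFeatureNames)))
    msgs <- c(msgs,
              "feature columns must be metFeatureNames then pwFeatureNames")
  if (n > 0 &&
      anyDuplicated(paste(object@metaboliteIds, object@pathwayIds,
                          sep = "\r")))
    msgs <- c(msgs, "every (metabolite, pathway) pair must appear once")
  if (length(object@features@x) && min(object@features@x) < 0)
    msgs <- c(msgs, "feature values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("features", "PairedDataset", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("entryLabels", "PairedDataset", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("metaboliteIds", "PairedDataset", function(x) x@metaboliteIds)
#' @rdname accessors
#' @export
setMethod("pathwayIds", "PairedDataset", function(x) x@pathwayIds)
#' @rdname accessors
#' @export
setMethod("entryLevels", "PairedDataset", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("pathwayInfo", "PairedDataset", function(x) x@pathwayInfo)
#' @rdname accessors
#' @export
setMethod("provenance", "PairedDataset", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("nEntries", "PairedDataset", function(x) nrow(x@features))
#' @rdname accessors
#' @export
setMethod("metFeatureNames", "PairedDataset", function(x) x@metFeatureNames)
#' @rdname accessors
#' @export
setMethod("pwFeatureNames", "PairedDataset", function(x) x@pwFeatureNames)

#' Subset a PairedDataset by entry
#'
#' @param x A [PairedDataset-class].
#' @param i Entry indices (integer or logical).
#' @param j,...,drop Ignored.
#' @return A [PairedDataset-class] holding the selected entries; the pathway
#'   table is restricted to pathways still present.
#' @export
setMethod("[", "PairedDataset", function(x, i, j, ..., drop = FALSE) {
  pw <- unique(x@pathwayIds[i])
  methods::initialize(x,
    features = x@features[i, , drop = FALSE],
    labels = x@labels[i],
    metaboliteIds = x@metaboliteIds[i],
    pathwayIds = x@pathwayIds[i],
    levels = x@levels[i],
    pathwayInfo = x@pathwayInfo[x@pathwayInfo$pathway_id %in% pw, ,
                                drop = FALSE])
})

setMethod("show", "PairedDataset", function(object) {
  cat(sprintf(paste0("PairedDataset: %d entries (%d metabolites x %d ",
                     "pathways), %d positive\n"),
              nEntries(object), length(unique(object@metaboliteIds)),
              length(unique(object@pathwayIds)), sum(object@labels)))
  cat(sprintf("  features: %d metabolite + %d pathway columns%s\n",
              length(object@metFeatureNames), length(object@pwFeatureNames),
              if (isTRUE(object@provenance$scaled)) " (min/max scaled)"
              else ""))
  lv <- table(object@pathwayInfo$level)
  cat("  levels:",
      paste(sprintf("%s=%d", names(lv), as.integer(lv)), collapse = " "),
      "\n")
})

#' MLPClassifier: a trained feed-forward membership classifier
#'
#' A fully-connected network with ReLU hidden layers and a sigmoid output
#' unit, trained by mini-batch gradient descent (Adam) on binary
#' cross-entropy. Prediction enforces the feature-name contract the model
#' was trained on: input columns are re-ordered by name and any mismatch in
#' the column set is an error.
#'
#' @slot layers List of `list(W, b)` weight matrices / bias vectors.
#' @slot hp Hyperparameter list (see [mlpHyperparameters()]).
#' @slot featureNames Ordered column contract.
#' @slot history `data.frame` of per-epoch training loss and validation MCC.
#' @slot epochsRun Number of epochs actually run (early stopping may trigger
#'   before `maxEpochs`).
#'
#' @seealso [trainClassifier()], [predict,MLPClassifier-method]
#' @export
setClass("MLPClassifier",
         representation(layers = "list",
                        hp = "list",
                        featureNames = "character",
                        history = "data.frame",
                        epochsRun = "integer"))

#' @rdname accessors
#' @export
setMethod("featureNames", "MLPClassifier", function(x) x@featureNames)
#' @rdname accessors
#' @export
setMethod("hyperparameters", "MLPClassifier", function(x) x@hp)
#' @rdname accessors
#' @export
setMethod("trainingHistory", "MLPClassifier", function(x) x@history)

setMethod("show", "MLPClassifier", function(object) {
  sizes <- vapply(object@layers, function(l) ncol(l$W), integer(1))
  cat(sprintf("MLPClassifier: %d -> %s (sigmoid), %d epochs run\n",
              length(object@featureNames),
              paste(sizes, collapse = " -> "), object@epochsRun))
})

#' CVResult: Monte-Carlo cross-validation results
#'
#' Per-iteration overall metrics plus per-(iteration, pathway) confusion
#' counts, which are additive: summing the per-pathway counts of an
#' iteration reproduces that iteration's overall confusion matrix, and
#' summing across iterations yields the overall per-pathway confusion
#' matrices from which single per-pathway MCCs are computed.
#'
#' @slot iterationMetrics `data.frame`: iteration, tp, tn, fp, fn, accuracy,
#'   precision, recall, f1, mcc.
#' @slot pathwayCounts `data.frame`: iteration, pathway_id, level, tp, tn,
#'   fp, fn.
#' @slot pathwayInfo Pathway table of the evaluated dataset.
#' @slot provenance List (seeds, hyperparameters, scaling flag, sizes).
#'
#' @seealso [runCV()], [pathwayOverallMCC()], [levelOverallMCC()]
#' @export
setClass("CVResult",
         representation(iterationMetrics = "data.frame",
                        pathwayCounts = "data.frame",
                        pathwayInfo = "data.frame",
                        provenance = "list"))

setValidity("CVResult", function(object) {
  need1 <- c("iteration", "tp", "tn", "fp", "fn",
             "accuracy", "precision", "recall", "f1", "mcc")
  need2 <- c("iteration", "pathway_id", "level", "tp", "tn", "fp", "fn")
  msgs <- character()
  if (!all(need1 %in% names(object@iterationMetrics)))
    msgs <- c(msgs, "iterationMetrics missing required columns")
  if (!all(need2 %in% names(object@pathwayCounts)))
    msgs <- c(msgs, "pathwayCounts missing required columns")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("iterationMetrics", "CVResult", function(x) x@iterationMetrics)
#' @rdname accessors
#' @export
setMethod("pathwayCounts", "CVResult", function(x) x@pathwayCounts)
#' @rdname accessors
#' @export
setMethod("pathwayInfo", "CVResult", function(x) x@pathwayInfo)
#' @rdname accessors
#' @export
setMethod("provenance", "CVResult", function(x) x@provenance)

setMethod("show", "CVResult", function(object) {
  m <- object@iterationMetrics$mcc
  cat(sprintf("CVResult: %d iterations, mean MCC %.3f (sd %.3f)\n",
              nrow(object@iterationMetrics), mean(m), stats::sd(m)))
  cat(sprintf("  pathway counts: %d rows over %d pathways\n",
              nrow(object@pathwayCounts),
              length(unique(object@pathwayCounts$pathway_id))))
})
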