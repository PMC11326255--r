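#' @include utils.R
NULL

#' Accessor generics
#'
#' Accessors for the core S4 classes: [MolecularGraph-class],
#' [CountVector-class], [PairedDataset-class], [MLPClassifier-class] and
#' [CVResult-class]. Slots are never accessed directly by user code.
#'
#' @param x An object of the relevant class.
#' @return The corresponding slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metaboliteId", function(x) standardGeneric("metaboliteId"))

#' @rdname accessors
#' @export
setGeneric("entityId", function(x) standardGeneric("entityId"))

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname accessors
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname accessors
#' @export
setGeneric("bondCount", function(x) standardGeneric("bondCount"))

#' @rdname accessors
#' @export
setGeneric("colorCounts", function(x) standardGeneric("colorCounts"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("entryLabels", function(x) standardGeneric("entryLabels"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname accessors
#' @export
setGeneric("entryLevels", function(x) standardGeneric("entryLevels"))

#' @rdname accessors
#' @export
setGeneric("pathwayInfo", function(x) standardGeneric("pathwayInfo"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("nEntries", function(x) standardGeneric("nEntries"))

#' @rdname accessors
#' @export
setGeneric("metFeatureNames", function(x) standardGeneric("metFeatureNames"))

#' @rdname accessors
#' @export
setGeneric("pwFeatureNames", function(x) standardGeneric("pwFeatureNames"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("hyperparameters", function(x) standardGeneric("hyperparameters"))

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setGeneric("iterationMetrics", function(x) standardGeneric("iterationMetrics"))

#' @rdname accessors
#' @export
setGeneric("pathwayCounts", function(x) standardGeneric("pathwayCounts"))

#' Train the pairwise membership classifier
#'
#' @param x Training data: a [PairedDataset-class] or a numeric /
#'   sparse feature matrix (entries in rows, named feature columns).
#' @param hp Hyperparameters from [mlpHyperparameters()].
#' @param ... Method-specific arguments; for the matrix method, `labels`
#'   (binary integer vector) is required.
#' @return An [MLPClassifier-class].
#' @export
setGeneric("trainClassifier", function(x, hp = mlpHyperparameters(), ...)
  standardGeneric("trainClassifier"))

#' Filter pathways by size
#'
#' Retains exactly the pathways whose size under the chosen metric is
#' greater than or equal to `threshold` (inclusive semantics, matching the
#' "at least N associated metabolites" reading), together with all of their
#' cross-join entries, both positive and negative.
#'
#' @param x A [PairedDataset-class] or a pathway-information `data.frame`
#'   with columns `size_compounds` and `size_atoms`.
#' @param threshold Non-negative integer size threshold.
#' @param metric `"compounds"` (member metabolite count) or `"atoms"`
#'   (summed non-hydrogen atoms over members).
#' @return Object of the same class as `x`, restricted to retained pathways.
#' @export
setGeneric("filterPathwaysBySize",
           function(x, threshold, metric = c("compounds", "atoms"))
             standardGeneric("filterPathwaysBySize"))
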