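#' @include mlp.R
NULL

#' Stratified train/test split of a paired dataset
#'
#' Repeated-random-subsampling splits: the test set holds the rounded
#' `testFraction` of all entries, allocated across strata by
#' largest-remainder apportionment so that every stratum's test share is
#' within one entry of the nominal fraction (ties between equal remainders
#' are broken at random under the seed). The default stratification key is
#' `(pathway_id, label)`, so each pathway contributes positives and
#' negatives to the test set in proportion; the key can be coarsened to
#' `label` only when strata are too small.
#'
#' @param dataset A [PairedDataset-class].
#' @param testFraction Fraction of entries sampled into the test set.
#' @param seed Integer seed; the split manifest is identical across runs
#'   with the same seed.
#' @param key `"pathway_label"` (default) or `"label"`.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   union = all entries) and a `manifest` `data.frame` (entry, stratum,
#'   set).
#' @export
stratifiedSplit <- function(dataset, testFraction = 0.10, seed = 1L,
                            key = c("pathway_label", "label")) {
  key <- match.arg(key)
  .assertScalarNumber(testFraction, "testFraction", lower = 1e-9,
                      upper = 1 - 1e-9)
  n <- nEntries(dataset)
  strata <- if (key == "pathway_label")
    paste(pathwayIds(dataset), entryLabels(dataset), sep = "|")
  else as.character(entryLabels(dataset))
  idxByStratum <- split(seq_len(n), strata)
  sizes <- lengths(idxByStratum)
  if (any(sizes < 2L))
    .stopf("metpairs_split_error",
           paste0("stratum too small (need >= 2 entries): %s; consider ",
                  "key = 'label'"),
           paste(utils::head(names(sizes)[sizes < 2L], 10), collapse = ", "))
  set.seed(seed)
  nTest <- round(testFraction * n)
  raw <- testFraction * sizes
  base <- floor(raw)
  rem <- nTest - sum(base)
  extra <- integer(length(sizes))
  if (rem > 0) {
    ord <- order(-(raw - base), sample.int(length(sizes)))
    extra[ord[seq_len(rem)]] <- 1L
  }
  take <- pmin(base + extra, sizes - 1L)  # never empty a stratum's train side
  testIdx <- unlist(lapply(seq_along(idxByStratum), function(k) {
    if (take[k] == 0L) return(integer())
    s <- idxByStratum[[k]]
    s[sample.int(length(s), take[k])]
  }), use.names = FALSE)
  testIdx <- sort(testIdx)
  manifest <- data.frame(entry = seq_len(n), stratum = strata,
                         set = "train")
  manifest$set[testIdx] <- "test"
  list(train = setdiff(seq_len(n), testIdx), test = testIdx,
       manifest = manifest)
}

#' Confusion counts of a prediction
#'
#' @param predicted,truth Binary 0/1 vectors of equal length.
#' @return Named integer vector `c(tp, tn, fp, fn)`; counts are additive
#'   under summation across iterations and pathways.
#' @export
confusionCounts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  c(tp = sum(predicted == 1L & truth == 1L),
    tn = sum(predicted == 0L & truth == 0L),
    fp = sum(predicted == 1L & truth == 0L),
    fn = sum(predicted == 0L & truth == 1L))
}

#' The five evaluation metrics from a confusion matrix
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient, `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' Any zero factor in the MCC denominator yields the defined value 0 (the
#' no-correlation convention for degenerate single-class cases);
#' precision, recall and F1 likewise return 0 on zero denominators.
#'
#' @param counts Named vector or one-row `data.frame`/list with elements
#'   `tp`, `tn`, `fp`, `fn` (total > 0).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `mcc`.
#' @examples
#' classificationMetrics(c(tp = 2, tn = 2, fp = 1, fn = 1))  # mcc = 1/3
#' @export
classificationMetrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  total <- tp + tn + fp + fn
  if (total <= 0)
    .stopf("metpairs_metric_error", "empty confusion counts")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = f1,
    mcc = .mccValue(tp, tn, fp, fn))
}

#' Monte-Carlo cross-validation of the pairwise classifier
#'
#' For each iteration: a fresh stratified split, feature-wise min/max
#' scaling fit on the training split only (when `scale = TRUE`), model
#' training, prediction on the test split, and recording of the overall
#' metrics plus the per-pathway confusion counts of the test entries. The
#' per-iteration seed is `baseSeed + iteration` for every random stage
#' (split, initialization, batching).
#'
#' @param dataset A [PairedDataset-class] (entry-wise normalized,
#'   unscaled; see [buildPairedDataset()]).
#' @param nIterations Number of independent split/train/test iterations.
#' @param hp [mlpHyperparameters()]; its `seed` field is overridden per
#'   iteration.
#' @param baseSeed Integer base seed.
#' @param scale Apply min/max scaling (fit on train) per iteration.
#' @param testFraction Fraction of entries sampled into each test set.
#' @param stratifyKey Passed to [stratifiedSplit()].
#' @return A [CVResult-class].
#' @export
runCV <- function(dataset, nIterations = 100L, hp = mlpHyperparameters(),
                  baseSeed = 1L, scale = TRUE, testFraction = 0.10,
                  stratifyKey = c("pathway_label", "label")) {
  stratifyKey <- match.arg(stratifyKey)
  if (nIterations < 1L)
    .stopf("metpairs_config_error", "nIterations must be >= 1")
  info <- pathwayInfo(dataset)
  lvl <- info$level
  names(lvl) <- info$pathway_id
  iterRows <- vector("list", nIterations)
  pwRows <- vector("list", nIterations)
  for (iter in seq_len(nIterations)) {
    seed <- baseSeed + iter
    res <- tryCatch({
      split <- stratifiedSplit(dataset, testFraction = testFraction,
                               seed = seed, key = stratifyKey)
      ds <- if (scale) minmaxScale(dataset, fitOn = split$train) else dataset
      hpIter <- hp
      hpIter$seed <- seed
      clf <- trainClassifier(ds[split$train], hpIter)
      test <- ds[split$test]
      pred <- predict(clf, test)
      truth <- entryLabels(test)
      cc <- confusionCounts(pred$label, truth)
      m <- classificationMetrics(cc)
      ## per-pathway confusion counts of this iteration's test entries
      ind <- cbind(tp = as.integer(pred$label == 1L & truth == 1L),
                   tn = as.integer(pred$label == 0L & truth == 0L),
                   fp = as.integer(pred$label == 1L & truth == 0L),
                   fn = as.integer(pred$label == 0L & truth == 1L))
      byPw <- rowsum(ind, group = pathwayIds(test))
      list(cc = cc, m = m, byPw = byPw)
    }, metpairs_error = function(e) {
      .stopf("metpairs_cv_error", "iteration %d: %s", iter,
             conditionMessage(e))
    })
    iterRows[[iter]] <- data.frame(iteration = iter,
                                   tp = res$cc[["tp"]], tn = res$cc[["tn"]],
                                   fp = res$cc[["fp"]], fn = res$cc[["fn"]],
                                   t(res$m))
    pwRows[[iter]] <- data.frame(iteration = iter,
                                 pathway_id = rownames(res$byPw),
                                 level = unname(lvl[rownames(res$byPw)]),
                                 tp = res$byPw[, "tp"],
                                 tn = res$byPw[, "tn"],
                                 fp = res$byPw[, "fp"],
                                 fn = res$byPw[, "fn"],
                                 row.names = NULL)
  }
  methods::new("CVResult",
               iterationMetrics = do.call(rbind, iterRows),
               pathwayCounts = do.call(rbind, pwRows),
               pathwayInfo = info[c("pathway_id", "level", "size_compounds",
                                    "size_atoms")],
               provenance = list(baseSeed = baseSeed,
                                 nIterations = nIterations,
                                 testFraction = testFraction,
                                 scaled = scale,
                                 stratifyKey = stratifyKey,
                                 hp = unclass(hp)))
}

#' Overall per-pathway MCC from summed confusion matrices
#'
#' Per pathway, the confusion counts are summed across all CV iterations
#' and a single MCC is computed from the summed matrix. This avoids the
#' division-by-zero hazard of per-iteration per-pathway MCCs for small
#' pathways (no standard deviation exists for these single values).
#' Pathways that never appeared in any test split are omitted with a
#' warning.
#'
#' @param cv A [CVResult-class].
#' @return `data.frame` with one row per pathway: `pathway_id`, `level`,
#'   `tp`, `tn`, `fp`, `fn`, `overall_mcc`, `size_compounds`, `size_atoms`.
#' @export
pathwayOverallMCC <- function(cv) {
  pc <- pathwayCounts(cv)
  summed <- rowsum(pc[c("tp", "tn", "fp", "fn")], group = pc$pathway_id)
  info <- pathwayInfo(cv)
  absent <- setdiff(info$pathway_id, rownames(summed))
  if (length(absent))
    .warnf("pathway(s) absent from every test split, score omitted: %s",
           paste(absent, collapse = ", "))
  ord <- .radixSort(rownames(summed))
  summed <- summed[ord, , drop = FALSE]
  at <- match(ord, info$pathway_id)
  data.frame(pathway_id = ord,
             level = info$level[at],
             tp = summed$tp, tn = summed$tn, fp = summed$fp, fn = summed$fn,
             overall_mcc = mapply(.mccValue, summed$tp, summed$tn,
                                  summed$fp, summed$fn),
             size_compounds = info$size_compounds[at],
             size_atoms = info$size_atoms[at],
             row.names = NULL)
}

#' Overall MCC of one hierarchy level
#'
#' Sums the confusion counts over all pathways of the given level and all
#' CV iterations, then computes a single MCC from the summed matrix.
#'
#' @param cv A [CVResult-class].
#' @param level `"L2"` or `"L3"`.
#' @return A single numeric MCC.
#' @export
levelOverallMCC <- function(cv, level) {
  pc <- pathwayCounts(cv)
  rows <- pc[pc$level == level, , drop = FALSE]
  if (nrow(rows) == 0L)
    .stopf("metpairs_metric_error",
           "no pathways at hierarchy level '%s'", level)
  .mccValue(sum(rows$tp), sum(rows$tn), sum(rows$fp), sum(rows$fn))
}

#' Correlation between pathway size and overall pathway MCC
#'
#' Four correlations, mirroring the size-versus-performance analysis:
#' Spearman rank correlation of size against MCC on the regular scale, and
#' Pearson correlation of log10(size) against MCC, each for both size
#' metrics (member compound count and summed non-hydrogen atoms). P-values
#' use the standard asymptotic approximations; no multiple-testing
#' correction is applied.
#'
#' @param scores Output of [pathwayOverallMCC()] (>= 3 rows).
#' @return `data.frame`: `size_metric`, `scale`, `method`, `estimate`,
#'   `p_value`.
#' @export
sizeMccCorrelation <- function(scores) {
  if (nrow(scores) < 3L)
    .stopf("metpairs_metric_error",
           "need at least 3 pathway scores for correlations")
  if (stats::sd(scores$overall_mcc) == 0)
    .stopf("metpairs_metric_error", "MCC scores are constant")
  one <- function(sizes, metric) {
    if (stats::sd(sizes) == 0)
      .stopf("metpairs_metric_error", "pathway sizes are constant")
    sp <- suppressWarnings(
      stats::cor.test(sizes, scores$overall_mcc, method = "spearman",
                      exact = FALSE))
    pe <- stats::cor.test(log10(sizes), scores$overall_mcc,
                          method = "pearson")
    data.frame(size_metric = metric,
               scale = c("regular", "log10"),
               method = c("spearman", "pearson"),
               estimate = c(unname(sp$estimate), unname(pe$estimate)),
               p_value = c(sp$p.value, pe$p.value))
  }
  rbind(one(scores$size_compounds, "compounds"),
        one(scores$size_atoms, "atoms"))
}

#' Overall MCC after filtering small pathways from the calculation
#'
#' At each threshold, the confusion counts of the pathways whose size is at
#' least the threshold are summed into one matrix and a single MCC is
#' computed (the model is *not* retrained; compare
#' [trainingFilterSweep()]). Threshold 0 reproduces the global overall MCC
#' across all pathways.
#'
#' @param scores Output of [pathwayOverallMCC()] (per-pathway summed
#'   counts and sizes).
#' @param thresholds Ascending integer size thresholds.
#' @param metric `"compounds"` or `"atoms"`.
#' @return `data.frame`: `threshold`, `mcc`, `n_pathways`. The curve
#'   truncates with a warning at the first threshold retaining no pathway.
#' @export
mccByMetricThreshold <- function(scores, thresholds,
                                 metric = c("compounds", "atoms")) {
  metric <- match.arg(metric)
  if (is.unsorted(thresholds))
    .stopf("metpairs_metric_error", "thresholds must be sorted ascending")
  sizes <- if (metric == "compounds") scores$size_compounds else
    scores$size_atoms
  rows <- list()
  for (t in thresholds) {
    keep <- sizes >= t
    if (!any(keep)) {
      .warnf("threshold %s retains no pathway; curve truncated", format(t))
      break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = t,
      mcc = .mccValue(sum(scores$tp[keep]), sum(scores$tn[keep]),
                      sum(scores$fp[keep]), sum(scores$fn[keep])),
      n_pathways = sum(keep))
  }
  do.call(rbind, rows)
}

#' Training-set pathway-size filter sweep
#'
#' Retrains the model on training universes from which pathways below each
#' size threshold were removed, and reports, for every threshold, the
#' overall MCC restricted to one fixed evaluation pathway set (so all
#' thresholds are comparable). This measures how excluding small pathways
#' from *training* — not merely from the MCC calculation — affects the
#' performance of the retained large pathways.
#'
#' @param dataset A [PairedDataset-class].
#' @param thresholds Ascending size thresholds; every threshold must retain
#'   all `evalSet` pathways.
#' @param evalSet Pathway ids the reported MCC is restricted to (e.g. the
#'   pathways surviving the largest threshold).
#' @param nIterations,hp,baseSeed,scale,testFraction,stratifyKey Passed to
#'   [runCV()] for each threshold.
#' @param metric Size metric used for filtering.
#' @return `data.frame`: `threshold`, `n_pathways_trained`, `mcc`.
#' @export
trainingFilterSweep <- function(dataset, thresholds, evalSet,
                                nIterations = 10L,
                                hp = mlpHyperparameters(),
                                baseSeed = 1L, scale = TRUE,
                                testFraction = 0.10,
                                stratifyKey = c("pathway_label", "label"),
                                metric = c("compounds", "atoms")) {
  metric <- match.arg(metric)
  stratifyKey <- match.arg(stratifyKey)
  rows <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    ds <- filterPathwaysBySize(dataset, t, metric)
    kept <- pathwayInfo(ds)$pathway_id
    missing <- setdiff(evalSet, kept)
    if (length(missing))
      .stopf("metpairs_metric_error",
             "threshold %s filters out evaluation pathway(s): %s",
             format(t), paste(missing, collapse = ", "))
    cv <- runCV(ds, nIterations = nIterations, hp = hp,
                baseSeed = baseSeed, scale = scale,
                testFraction = testFraction, stratifyKey = stratifyKey)
    pc <- pathwayCounts(cv)
    pc <- pc[pc$pathway_id %in% evalSet, , drop = FALSE]
    rows[[k]] <- data.frame(
      threshold = t,
      n_pathways_trained = length(kept),
      mcc = .mccValue(sum(pc$tp), sum(pc$tn), sum(pc$fp), sum(pc$fn)))
  }
  do.call(rbind, rows)
}

#' Persist / load cross-validation results
#'
#' Writes the result tables as TSV (`iteration_metrics.tsv`,
#' `pathway_counts.tsv`, `pathway_info.tsv`) plus `provenance.json`, the
#' persisted form over which independent reconciliation checks (global =
#' sum over levels = sum over pathways) can be run.
#'
#' @param cv A [CVResult-class].
#' @param dir Output (input) directory.
#' @return `writeCVResult()` returns `dir` invisibly; `readCVResult()` the
#'   restored [CVResult-class].
#' @export
writeCVResult <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTSV(iterationMetrics(cv), file.path(dir, "iteration_metrics.tsv"))
  .writeTSV(pathwayCounts(cv), file.path(dir, "pathway_counts.tsv"))
  .writeTSV(pathwayInfo(cv), file.path(dir, "pathway_info.tsv"))
  .writeJSON(provenance(cv), file.path(dir, "provenance.json"))
  invisible(dir)
}

#' @rdname writeCVResult
#' @export
readCVResult <- function(dir) {
  methods::new("CVResult",
               iterationMetrics = .readTSV(file.path(dir,
                                                     "iteration_metrics.tsv")),
               pathwayCounts = .readTSV(file.path(dir, "pathway_counts.tsv")),
               pathwayInfo = .readTSV(file.path(dir, "pathway_info.tsv")),
               provenance = as.list(.readJSON(file.path(dir,
                                                        "provenance.json"))))
}
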