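test_that("stratified splits hold the stated fraction per stratum", {
  ds <- tinyDataset(seed = 41, nMet = 100L, n3 = 5L, n2 = 0L)
  expect_identical(nEntries(ds), 500L)
  sp <- stratifiedSplit(ds, testFraction = 0.10, seed = 3)
  expect_identical(length(sp$test), 50L)             # round(0.1 * 500)
  expect_identical(sort(c(sp$train, sp$test)), seq_len(500L))
  # per-stratum share within one entry of 10%
  strata <- paste(pathwayIds(ds), entryLabels(ds), sep = "|")
  for (s in unique(strata)) {
    idx <- which(strata == s)
    got <- sum(idx %in% sp$test)
    expect_lte(abs(got - 0.1 * length(idx)), 1)
  }
  # identical manifest under the same seed
  sp2 <- stratifiedSplit(ds, testFraction = 0.10, seed = 3)
  expect_identical(sp$manifest, sp2$manifest)
  # a different seed draws a different split
  sp3 <- stratifiedSplit(ds, testFraction = 0.10, seed = 4)
  expect_false(identical(sp$test, sp3$test))
})

test_that("too-small strata error and the label-only key coarsens", {
  toy <- toySeparable(40, seed = 43)
  ds <- methods::new("PairedDataset", features = toy$X,
                     labels = toy$y,
                     metaboliteIds = paste0("m", 1:40),
                     pathwayIds = c("lonely", rep("p", 39)),
                     levels = rep("L3", 40),
                     metFeatureNames = "f1", pwFeatureNames = "f2",
                     pathwayInfo = data.frame(
                       pathway_id = c("lonely", "p"), level = "L3",
                       size_compounds = c(1L, 20L),
                       size_atoms = c(5L, 100L)),
                     provenance = list())
  expect_error(stratifiedSplit(ds, 0.2, seed = 1), "lonely",
               class = "metpairs_split_error")
  sp <- stratifiedSplit(ds, 0.2, seed = 1, key = "label")
  expect_identical(length(sp$test), 8L)
})

test_that("the five metrics match their definitions", {
  perfect <- classificationMetrics(c(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(perfect["mcc"]), 1)
  expect_equal(unname(perfect["accuracy"]), 1)
  m <- classificationMetrics(c(tp = 2, tn = 2, fp = 1, fn = 1))
  expect_equal(unname(m["mcc"]), 3 / 9)
  expect_equal(unname(m["accuracy"]), 4 / 6)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 2 / 3)
  expect_equal(unname(m["f1"]), 2 / 3)
  # degenerate single-class test set: defined value 0
  z <- classificationMetrics(c(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_identical(unname(z["mcc"]), 0)
  expect_identical(unname(z["precision"]), 0)
  expect_error(classificationMetrics(c(tp = 0, tn = 0, fp = 0, fn = 0)),
               class = "metpairs_metric_error")
})

test_that("MCC agrees with the phi-correlation oracle on random matrices", {
  set.seed(47)
  for (k in 1:200) {
    cts <- rpois(4, lambda = sample(c(0.5, 3, 20), 1))
    names(cts) <- c("tp", "tn", "fp", "fn")
    if (sum(cts) == 0) cts["tn"] <- 1
    got <- unname(classificationMetrics(cts)["mcc"])
    expect_equal(got, mccByCorrelation(cts["tp"], cts["tn"], cts["fp"],
                                       cts["fn"]),
                 tolerance = 1e-12)
  }
})

cvFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- tinyDataset(seed = 51, nMet = 80L, n3 = 5L, n2 = 2L)
      cache <<- list(ds = ds,
                     cv = runCV(ds, nIterations = 3L, hp = cheapHp(),
                                baseSeed = 7))
    }
    cache
  }
})

test_that("per-pathway confusion counts reconcile with iteration totals", {
  fx <- cvFixture()
  im <- iterationMetrics(fx$cv)
  pc <- pathwayCounts(fx$cv)
  for (it in im$iteration) {
    sub <- pc[pc$iteration == it, ]
    for (f in c("tp", "tn", "fp", "fn"))
      expect_identical(sum(sub[[f]]), im[[f]][im$iteration == it])
  }
  # level matrices sum to the global matrix
  for (f in c("tp", "tn", "fp", "fn"))
    expect_identical(sum(pc[[f]][pc$level == "L2"]) +
                       sum(pc[[f]][pc$level == "L3"]),
                     sum(im[[f]]))
})

test_that("cross-validation is deterministic given its seeds", {
  fx <- cvFixture()
  cv2 <- runCV(fx$ds, nIterations = 3L, hp = cheapHp(), baseSeed = 7)
  expect_identical(iterationMetrics(fx$cv), iterationMetrics(cv2))
  expect_identical(pathwayCounts(fx$cv), pathwayCounts(cv2))
})

test_that("overall pathway MCC is computed from summed matrices", {
  fx <- cvFixture()
  scores <- pathwayOverallMCC(fx$cv)
  pc <- pathwayCounts(fx$cv)
  for (p in scores$pathway_id) {
    sub <- pc[pc$pathway_id == p, ]
    expect_equal(scores$overall_mcc[scores$pathway_id == p],
                 mccByCorrelation(sum(sub$tp), sum(sub$tn),
                                  sum(sub$fp), sum(sub$fn)),
                 tolerance = 1e-12)
  }
  expect_true(all(scores$overall_mcc >= -1 & scores$overall_mcc <= 1))
})

test_that("MCC of summed matrices is scale invariant", {
  # summing k identical matrices leaves the MCC unchanged, exactly
  one <- classificationMetrics(c(tp = 2, tn = 2, fp = 1, fn = 1))["mcc"]
  three <- classificationMetrics(c(tp = 6, tn = 6, fp = 3, fn = 3))["mcc"]
  expect_identical(one, three)
  # the worked sum: {2,2,1,1} + {3,3,0,0} -> {5,5,1,1}
  summed <- classificationMetrics(c(tp = 5, tn = 5, fp = 1, fn = 1))
  expect_equal(unname(summed["mcc"]), 24 / 36)
})

test_that("level MCC equals the total in a one-level dataset and is additive", {
  ds <- tinyDataset(seed = 53, nMet = 60L, n3 = 4L, n2 = 0L)
  cv <- runCV(ds, nIterations = 2L, hp = cheapHp(), baseSeed = 3)
  im <- iterationMetrics(cv)
  expect_equal(levelOverallMCC(cv, "L3"),
               unname(classificationMetrics(c(
                 tp = sum(im$tp), tn = sum(im$tn),
                 fp = sum(im$fp), fn = sum(im$fn)))["mcc"]))
  expect_error(levelOverallMCC(cv, "L2"), class = "metpairs_metric_error")
})

test_that("size-MCC correlations match independent formulas", {
  # hand-built 5-point dataset
  scores <- data.frame(pathway_id = paste0("p", 1:5), level = "L3",
                       tp = 1, tn = 1, fp = 1, fn = 1,
                       overall_mcc = c(0.2, 0.5, 0.4, 0.8, 0.7),
                       size_compounds = c(3, 10, 8, 50, 30),
                       size_atoms = c(30, 90, 85, 600, 310))
  out <- sizeMccCorrelation(scores)
  expect_identical(nrow(out), 4L)
  sp <- out[out$method == "spearman" & out$size_metric == "compounds", ]
  # textbook Spearman: Pearson correlation of the ranks
  expect_equal(sp$estimate,
               stats::cor(rank(scores$size_compounds),
                          rank(scores$overall_mcc)))
  pe <- out[out$method == "pearson" & out$size_metric == "atoms", ]
  x <- log10(scores$size_atoms); y <- scores$overall_mcc
  expect_equal(pe$estimate,
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  # perfectly co-monotone scores give Spearman exactly 1
  mono <- scores
  mono$overall_mcc <- mono$size_compounds / 100
  expect_equal(sizeMccCorrelation(mono)$estimate[1], 1)
  expect_error(sizeMccCorrelation(scores[1:2, ]),
               class = "metpairs_metric_error")
})

test_that("permuted sizes show no correlation at n = 100", {
  set.seed(59)
  scores <- data.frame(pathway_id = paste0("p", 1:100), level = "L3",
                       tp = 1, tn = 1, fp = 1, fn = 1,
                       overall_mcc = runif(100, -0.2, 0.9),
                       size_compounds = sample(3:500, 100),
                       size_atoms = sample(30:5000, 100))
  out <- sizeMccCorrelation(scores)
  expect_true(all(abs(out$estimate) < 0.25))
  expect_true(all(out$p_value > 0.01))
})

test_that("the MCC-by-threshold curve reproduces brute-force sums", {
  fx <- cvFixture()
  scores <- pathwayOverallMCC(fx$cv)
  thr <- c(0, sort(sample(scores$size_compounds, 2)), 10000)
  expect_warning(curve <- mccByMetricThreshold(scores, thr, "compounds"),
                 "truncated")
  # threshold 0 equals the global overall MCC
  im <- iterationMetrics(fx$cv)
  expect_equal(curve$mcc[1],
               unname(classificationMetrics(c(
                 tp = sum(im$tp), tn = sum(im$tn),
                 fp = sum(im$fp), fn = sum(im$fn)))["mcc"]))
  # retained count non-increasing; brute-force agreement at each threshold
  expect_true(all(diff(curve$n_pathways) <= 0))
  for (r in seq_len(nrow(curve))) {
    keep <- scores$size_compounds >= curve$threshold[r]
    expect_identical(curve$n_pathways[r], sum(keep))
    expect_equal(curve$mcc[r],
                 mccByCorrelation(sum(scores$tp[keep]),
                                  sum(scores$tn[keep]),
                                  sum(scores$fp[keep]),
                                  sum(scores$fn[keep])),
                 tolerance = 1e-12)
  }
  expect_error(mccByMetricThreshold(scores, c(5, 0), "compounds"),
               class = "metpairs_metric_error")
})

test_that("the training filter sweep is anchored by the unfiltered run", {
  fx <- cvFixture()
  info <- pathwayInfo(fx$ds)
  evalSet <- info$pathway_id[order(-info$size_compounds)][1:3]
  sweep <- trainingFilterSweep(fx$ds, thresholds = c(0, 0), evalSet,
                               nIterations = 2L, hp = cheapHp(),
                               baseSeed = 7)
  # identical inputs and seeds at both thresholds give identical MCC
  expect_identical(sweep$mcc[1], sweep$mcc[2])
  expect_identical(sweep$n_pathways_trained[1], nrow(info))
  # threshold 0 equals restricting the full run's counts to the eval set
  cv <- runCV(fx$ds, nIterations = 2L, hp = cheapHp(), baseSeed = 7)
  pc <- pathwayCounts(cv)
  pc <- pc[pc$pathway_id %in% evalSet, ]
  expect_equal(sweep$mcc[1],
               mccByCorrelation(sum(pc$tp), sum(pc$tn),
                                sum(pc$fp), sum(pc$fn)),
               tolerance = 1e-12)
  # filtering away an evaluation pathway is an error
  small <- info$pathway_id[which.min(info$size_compounds)]
  expect_error(trainingFilterSweep(fx$ds,
                                   max(info$size_compounds), small,
                                   nIterations = 1L, hp = cheapHp()),
               class = "metpairs_metric_error")
})

test_that("persisted CV results reload identically", {
  fx <- cvFixture()
  dir <- withr::local_tempdir()
  writeCVResult(fx$cv, dir)
  back <- readCVResult(dir)
  expect_equal(iterationMetrics(back), iterationMetrics(fx$cv))
  expect_equal(pathwayCounts(back), pathwayCounts(fx$cv))
})
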