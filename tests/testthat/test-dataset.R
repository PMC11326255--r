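makeMembership <- function(pathways, level = "L3") {
  do.call(rbind, lapply(names(pathways), function(p)
    data.frame(pathway_id = p, level = level,
               metabolite_id = pathways[[p]])))
}

test_that("pathway definitions compute both size metrics", {
  graphs <- list(a = MolecularGraph("a", c("C", "C", "O"),
                                    rbind(c(1, 2, 1), c(2, 3, 1))),
                 b = MolecularGraph("b", c("C", "N"), rbind(c(1, 2, 1))),
                 c = MolecularGraph("c", "C", NULL))
  mem <- makeMembership(list(p1 = c("a", "b"), p2 = c("a", "b", "c")))
  info <- pathwayDefinitions(mem, graphs)
  expect_identical(info$size_compounds, c(2L, 3L))
  expect_identical(info$size_atoms, c(5L, 6L))
  expect_true(all(info$size_atoms >= info$size_compounds))
  expect_error(pathwayDefinitions(makeMembership(list(p = "zz")), graphs),
               "zz", class = "metpairs_dataset_error")
})

test_that("pathway features sum member count vectors", {
  graphs <- list(a = parseMolfile(ethanolMolfile(), "a"),
                 b = randomGraph(5, 91), c = randomGraph(7, 92))
  names(graphs) <- c("a", "rg91", "rg92")
  corpus <- lapply(graphs, colorAtoms)
  mem <- makeMembership(list(solo = "a",
                             both = c("a", "rg91", "rg92")))
  info <- pathwayDefinitions(mem, graphs)
  pw <- buildPathwayFeatures(info, corpus)
  # singleton pathway equals its member
  expect_identical(colorCounts(pw$solo), colorCounts(corpus$a))
  expect_identical(bondCount(pw$solo), bondCount(corpus$a))
  # brute-force oracle: add the three vectors color by color
  allColors <- sort(unique(unlist(lapply(corpus, function(cv)
    names(colorCounts(cv))))), method = "radix")
  expected <- vapply(allColors, function(col)
    sum(vapply(corpus, function(cv) {
      v <- colorCounts(cv)[col]
      if (is.na(v)) 0 else unname(v)
    }, numeric(1))), numeric(1))
  expect_equal(colorCounts(pw$both), expected[expected > 0])
  expect_identical(bondCount(pw$both),
                   sum(vapply(corpus, bondCount, integer(1))))
  # duplicated member doubles every count
  g2 <- graphs
  g2$a2 <- MolecularGraph("a2", atoms(graphs$a), bonds(graphs$a))
  corpus2 <- lapply(g2, colorAtoms)
  mem2 <- makeMembership(list(dup = c("a", "a2")))
  pwDup <- buildPathwayFeatures(pathwayDefinitions(mem2, g2), corpus2)
  expect_equal(colorCounts(pwDup$dup), colorCounts(corpus$a) * 2)
})

test_that("softmax by bond count matches the closed form", {
  sym <- softmaxByBondCount(CountVector("s", c(a = 1, b = 1), 2L))
  expect_equal(unname(colorCounts(sym)), c(0.5, 0.5))
  two <- softmaxByBondCount(CountVector("t", c(a = 2, b = 1), 1L))
  expect_equal(unname(colorCounts(two)[c("a", "b")]),
               c(exp(2), exp(1)) / (exp(2) + exp(1)), tolerance = 1e-12)
  expect_equal(unname(colorCounts(two)[c("a", "b")]),
               c(0.7310586, 0.2689414), tolerance = 1e-6)
  # single-atom entities (zero bonds) normalize with B = 1
  one <- softmaxByBondCount(CountVector("u", c(C = 1), 0L))
  expect_equal(unname(colorCounts(one)), 1)
  expect_error(softmaxByBondCount(CountVector("z", numeric(), 3L)),
               class = "metpairs_dataset_error")
})

test_that("softmax outputs are a distribution regardless of input", {
  set.seed(99)
  for (k in 1:20) {
    n <- sample(1:40, 1)
    cts <- sample(1:30, n, replace = TRUE)
    names(cts) <- paste0("col", sample.int(1e6, n))
    cv <- CountVector(paste0("e", k), cts, sample(0:50, 1))
    out <- colorCounts(softmaxByBondCount(cv))
    expect_true(all(out > 0 & out <= 1))
    expect_equal(sum(out), 1, tolerance = 1e-9)
    # invariant to color ordering
    cv2 <- CountVector(paste0("e", k), rev(cts), bondCount(cv))
    expect_equal(colorCounts(softmaxByBondCount(cv2)), out)
  }
})

test_that("cross join produces the full labeled Cartesian product", {
  metMat <- Matrix::sparseMatrix(i = 1:3, j = c(1, 2, 1), x = 1,
                                 dims = c(3, 2),
                                 dimnames = list(c("m1", "m2", "m3"),
                                                 c("f1", "f2")))
  pwMat <- Matrix::sparseMatrix(i = 1:2, j = c(1, 1), x = 1,
                                dims = c(2, 1),
                                dimnames = list(c("p1", "p2"), "f1"))
  mem <- data.frame(pathway_id = c("p1", "p1", "p2"),
                    level = c("L3", "L3", "L2"),
                    metabolite_id = c("m1", "m2", "m3"))
  ds <- crossJoin(metMat, pwMat, mem)
  expect_identical(nEntries(ds), 6L)
  key <- paste(metaboliteIds(ds), pathwayIds(ds))
  expect_identical(anyDuplicated(key), 0L)
  # labels reflect membership exactly
  expect_identical(entryLabels(ds)[match(c("m1 p1", "m2 p1", "m3 p2"), key)],
                   rep(1L, 3))
  expect_identical(sum(entryLabels(ds)), 3L)
  # namespaced feature blocks
  expect_identical(colnames(features(ds)),
                   c("met::f1", "met::f2", "pw::f1"))
  dup <- metMat
  rownames(dup) <- c("m1", "m1", "m3")
  expect_error(crossJoin(dup, pwMat, mem),
               class = "metpairs_dataset_error")
})

test_that("cross-join cardinality and positive bookkeeping hold for random sizes", {
  set.seed(4)
  for (k in 1:5) {
    M <- sample(3:12, 1); P <- sample(2:6, 1)
    metIds <- paste0("m", 1:M); pwIds <- paste0("p", 1:P)
    metMat <- Matrix::sparseMatrix(i = 1:M, j = rep(1, M), x = 1,
                                   dims = c(M, 1),
                                   dimnames = list(metIds, "f"))
    pwMat <- Matrix::sparseMatrix(i = 1:P, j = rep(1, P), x = 1,
                                  dims = c(P, 1),
                                  dimnames = list(pwIds, "f"))
    mem <- do.call(rbind, lapply(pwIds, function(p)
      data.frame(pathway_id = p, level = "L3",
                 metabolite_id = sample(metIds, sample(1:M, 1)))))
    ds <- crossJoin(metMat, pwMat, mem)
    expect_identical(nEntries(ds), M * P)
    # label-1 entries equal the summed pathway compound sizes
    expect_identical(sum(entryLabels(ds)), nrow(mem))
    expect_identical(sum(entryLabels(ds)),
                     sum(pathwayInfo(ds)$size_compounds))
  }
})

test_that("min/max scaling maps fit columns onto [0, 1] exactly", {
  X <- methods::as(Matrix::Matrix(c(0, 2, 4,
                                    3, 3, 3,
                                    1, 0, 5), 3, 3,
                                  dimnames = list(NULL,
                                                  c("a", "b", "c"))),
                   "CsparseMatrix")
  ds <- methods::new("PairedDataset", features = X,
                     labels = c(1L, 0L, 0L),
                     metaboliteIds = paste0("m", 1:3),
                     pathwayIds = rep("p", 3),
                     levels = rep("L3", 3),
                     metFeatureNames = c("a", "b"),
                     pwFeatureNames = "c",
                     pathwayInfo = data.frame(pathway_id = "p",
                                              level = "L3",
                                              size_compounds = 1L,
                                              size_atoms = 1L),
                     provenance = list())
  sc <- features(minmaxScale(ds))
  expect_equal(unname(as.numeric(sc[, "a"])), c(0, 0.5, 1))
  expect_equal(unname(as.numeric(sc[, "b"])), c(0, 0, 0))  # constant -> 0
  expect_equal(unname(as.numeric(sc[, "c"])), c(0.2, 0, 1))
  # fit on a subset clips out-of-range transforms into [0, 1]
  sc2 <- features(minmaxScale(ds, fitOn = 1:2))
  expect_true(all(sc2@x >= 0 & sc2@x <= 1))
  expect_equal(unname(as.numeric(sc2[, "a"])), c(0, 1, 1))  # 4 clipped
})

test_that("scaled training columns span [0, 1] on random sparse data", {
  set.seed(12)
  X <- Matrix::rsparsematrix(60, 30, density = 0.2,
                             rand.x = function(n) runif(n, 0, 5))
  X@x <- abs(X@x)
  colnames(X) <- paste0("f", 1:30)
  fit <- metpairs:::.minmaxFit(X, 1:40)
  out <- metpairs:::.minmaxApply(X, fit)
  expect_true(all(out@x >= 0 & out@x <= 1))
  dense <- as.matrix(out[1:40, ])
  nonConst <- apply(as.matrix(X[1:40, ]), 2, function(v) max(v) > min(v))
  expect_true(all(abs(apply(dense[, nonConst], 2, max) - 1) < 1e-12))
  expect_true(all(apply(dense[, nonConst], 2, min) == 0))
})

test_that("pathway size filtering keeps exactly the at-threshold pathways", {
  info <- data.frame(pathway_id = paste0("p", 1:4),
                     level = "L3",
                     size_compounds = c(3L, 5L, 12L, 100L),
                     size_atoms = c(30L, 50L, 120L, 1000L))
  expect_identical(filterPathwaysBySize(info, 0)$pathway_id,
                   info$pathway_id)           # threshold 0 is the identity
  expect_identical(filterPathwaysBySize(info, 12)$pathway_id,
                   c("p3", "p4"))             # inclusive >= semantics
  expect_identical(filterPathwaysBySize(info, 121, "atoms")$pathway_id,
                   "p4")
  expect_error(filterPathwaysBySize(info, 1e6),
               class = "metpairs_dataset_error")
})

test_that("dataset-level size filtering matches a brute-force filter", {
  ds <- tinyDataset(seed = 31)
  info <- pathwayInfo(ds)
  thr <- sort(info$size_compounds)[3]
  kept <- filterPathwaysBySize(ds, thr, "compounds")
  expected <- info$pathway_id[info$size_compounds >= thr]
  expect_setequal(unique(pathwayIds(kept)), expected)
  # all entries of retained pathways survive, both labels
  expect_identical(nEntries(kept),
                   sum(pathwayIds(ds) %in% expected))
  expect_identical(sum(entryLabels(kept)),
                   sum(entryLabels(ds)[pathwayIds(ds) %in% expected]))
})

test_that("paired datasets survive a disk round trip", {
  ds <- tinyDataset(seed = 8, nMet = 30L, n3 = 3L, n2 = 1L)
  dir <- withr::local_tempdir()
  writePairedDataset(ds, dir)
  back <- readPairedDataset(dir)
  expect_equal(as.matrix(features(back)), as.matrix(features(ds)))
  expect_identical(entryLabels(back), entryLabels(ds))
  expect_identical(metaboliteIds(back), metaboliteIds(ds))
  expect_identical(pathwayIds(back), pathwayIds(ds))
  expect_identical(pathwayInfo(back)$size_atoms, pathwayInfo(ds)$size_atoms)
})
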