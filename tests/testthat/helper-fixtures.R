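# Fixtures built in code: hand-written molfiles, tiny corpora, toy
# classification problems. Everything is generated at test time.

# Ethanol with explicit hydrogens (C2H6O): 9 atoms, 8 bonds.
ethanolMolfile <- function() {
  c("ethanol",
    "  test",
    "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0",
    "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0",
    "    0.0000    1.0000    0.0000 H   0  0  0  0  0  0",
    "    0.0000   -1.0000    0.0000 H   0  0  0  0  0  0",
    "   -1.0000    0.0000    0.0000 H   0  0  0  0  0  0",
    "    1.0000    1.0000    0.0000 H   0  0  0  0  0  0",
    "    1.0000   -1.0000    0.0000 H   0  0  0  0  0  0",
    "    2.0000    1.0000    0.0000 H   0  0  0  0  0  0",
    "  1  2  1  0",
    "  2  3  1  0",
    "  1  4  1  0",
    "  1  5  1  0",
    "  1  6  1  0",
    "  2  7  1  0",
    "  2  8  1  0",
    "  3  9  1  0",
    "M  END")
}

# The frozen atom-coloring enumeration for hydrogen-stripped ethanol
# (C1-C2-O3, single bonds), worked out by hand:
#   radius 0: C1 "C", C2 "C", O3 "O"
#   radius 1: C1 "C(1:C)", C2 "C(1:C,1:O)", O3 "O(1:C)"
#   radius 2 (eccentricity 2 atoms only, C1 and O3):
#             C1 "C(1:C(1:C,1:O))", O3 "O(1:C(1:C,1:O))"
ethanolExpectedColors <- function() {
  c("C" = 2, "C(1:C)" = 1, "C(1:C(1:C,1:O))" = 1, "C(1:C,1:O)" = 1,
    "O" = 1, "O(1:C)" = 1, "O(1:C(1:C,1:O))" = 1)
}

# Random valid molecular graph (spanning tree + extra edges).
randomGraph <- function(n, seed, elements = c("C", "N", "O")) {
  set.seed(seed)
  els <- sample(elements, n, replace = TRUE)
  bonds <- NULL
  if (n > 1) {
    parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
    bonds <- cbind(parent, 2:n, sample(1:3, n - 1, replace = TRUE))
  }
  MolecularGraph(paste0("rg", seed), els, bonds)
}

# Apply an atom-index permutation to a graph: new index of old atom i is
# perm[i]. Isomorphic by construction.
permuteGraph <- function(graph, perm) {
  n <- atomCount(graph)
  newAtoms <- character(n)
  newAtoms[perm] <- atoms(graph)
  b <- bonds(graph)
  if (nrow(b) > 0) {
    b[, 1] <- perm[b[, 1]]
    b[, 2] <- perm[b[, 2]]
  }
  MolecularGraph(metaboliteId(graph), newAtoms, b)
}

# Linearly separable toy problem: two informative feature columns.
toySeparable <- function(n, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- cbind(f1 = runif(n) * 0.2 + y * 0.8,
             f2 = runif(n) * 0.2 + (1 - y) * 0.8)
  list(X = methods::as(X, "CsparseMatrix"), y = y)
}

# Small synthetic universe + paired dataset for evaluation tests.
tinyDataset <- function(seed = 5, nMet = 80L, n3 = 5L, n2 = 2L,
                        signal = 1) {
  cfg <- generatorConfig(nMetabolites = nMet, nPathwaysL3 = n3,
                         nPathwaysL2 = n2, signalStrength = signal,
                         seed = seed)
  u <- generateUniverse(cfg)
  buildPairedDataset(u$graphs, u$membership)
}

# Cheap hyperparameters for tests that only need a working model.
cheapHp <- function(seed = 1, ...) {
  mlpHyperparameters(hiddenLayerSizes = 32L, learningRate = 3e-3,
                     batchSize = 512L, maxEpochs = 25L,
                     earlyStopPatience = 0L, dropout = 0,
                     inputDropout = 0.3, validationFraction = 0,
                     seed = seed, ...)
}

# Independent MCC oracle: reconstruct the binary prediction/truth vectors
# from the counts and take their Pearson correlation (phi coefficient).
mccByCorrelation <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  if (length(truth) == 0) return(NA_real_)
  r <- suppressWarnings(stats::cor(pred, truth))
  if (is.na(r)) 0 else r
}
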