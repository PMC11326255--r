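#' @include dataset.R
NULL

#' Hyperparameters for the MLP membership classifier
#'
#' The defaults (two hidden layers of 512 and 128 ReLU units, dropout 0.2,
#' batch size 1024, learning rate 1e-3, early stopping on validation MCC
#' with patience 5) are a reasonable desk-scale configuration; per-dataset
#' tuning is available through [tuneHyperparameters()]. Class imbalance is
#' handled by the cross-join construction itself (it multiplies the number
#' of positive examples), so no loss re-weighting is applied.
#'
#' @param hiddenLayerSizes Positive integers, one per hidden layer.
#' @param learningRate Positive Adam step size.
#' @param batchSize Positive mini-batch size (capped at the training size).
#' @param maxEpochs Maximum training epochs.
#' @param minEpochs Warm-up epochs during which early stopping cannot
#'   trigger (validation MCC commonly sits at 0 until the positive class
#'   starts being predicted at all).
#' @param earlyStopPatience Epochs without validation-MCC improvement before
#'   stopping; 0 disables early stopping (and the validation carve-out).
#' @param dropout Hidden-unit dropout probability in \[0, 1).
#' @param inputDropout Dropout probability applied to the input features
#'   during training; discourages memorization of entity-unique colors.
#' @param weightDecay L2 penalty (decoupled, AdamW-style) on the weights.
#' @param validationFraction Fraction of the training entries held out
#'   (stratified by label) to monitor validation MCC.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A validated hyperparameter list of class `"mlpHyperparameters"`.
#' @export
mlpHyperparameters <- function(hiddenLayerSizes = c(512L, 128L),
                               learningRate = 1e-3,
                               batchSize = 1024L,
                               maxEpochs = 100L,
                               minEpochs = 10L,
                               earlyStopPatience = 5L,
                               dropout = 0.2,
                               inputDropout = 0,
                               weightDecay = 0,
                               validationFraction = 0.1,
                               seed = 1L) {
  if (length(hiddenLayerSizes) < 1L || any(hiddenLayerSizes < 1))
    .stopf("metpairs_config_error",
           "hiddenLayerSizes must be positive integers")
  .assertScalarNumber(learningRate, "learningRate", lower = 1e-12)
  .assertScalarNumber(batchSize, "batchSize", lower = 1)
  .assertScalarNumber(maxEpochs, "maxEpochs", lower = 1)
  .assertScalarNumber(minEpochs, "minEpochs", lower = 0)
  .assertScalarNumber(earlyStopPatience, "earlyStopPatience", lower = 0)
  .assertScalarNumber(dropout, "dropout", lower = 0, upper = 1 - 1e-9)
  .assertScalarNumber(inputDropout, "inputDropout", lower = 0,
                      upper = 1 - 1e-9)
  .assertScalarNumber(weightDecay, "weightDecay", lower = 0)
  .assertScalarNumber(validationFraction, "validationFraction",
                      lower = 0, upper = 0.5)
  .assertScalarNumber(seed, "seed")
  structure(list(hiddenLayerSizes = as.integer(hiddenLayerSizes),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 minEpochs = as.integer(minEpochs),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 dropout = dropout,
                 inputDropout = inputDropout,
                 weightDecay = weightDecay,
                 validationFraction = validationFraction,
                 seed = as.integer(seed)),
            class = "mlpHyperparameters")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

## Forward pass. Returns the output probabilities and, when `cache = TRUE`,
## the per-layer pre-activations/activations/dropout masks for backprop.
.mlpForward <- function(layers, X, dropout = 0, training = FALSE,
                        cache = FALSE) {
  L <- length(layers)
  A <- X
  Zs <- vector("list", L)
  As <- vector("list", L)      # activations *entering* each layer
  Ms <- vector("list", L)
  for (l in seq_len(L)) {
    As[[l]] <- A
    W <- layers[[l]]$W
    Z <- as.matrix(A %*% W)
    Z <- Z + matrix(layers[[l]]$b, nrow(Z), ncol(Z), byrow = TRUE)
    if (l < L) {
      A <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix((stats::runif(length(A)) >= dropout) / (1 - dropout),
                    nrow(A), ncol(A))
        A <- A * m
        Ms[[l]] <- m
      }
    } else {
      A <- .sigmoid(Z)
    }
    Zs[[l]] <- Z
  }
  p <- as.numeric(A)
  if (!cache) return(p)
  list(p = p, Zs = Zs, As = As, Ms = Ms)
}

.mlpTrain <- function(X, y, hp) {
  if (is.null(colnames(X)))
    .stopf("metpairs_model_error", "training features must have column names")
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    .stopf("metpairs_model_error",
           "training set must contain both labels")
  set.seed(hp$seed)
  n <- nrow(X)

  ## validation carve-out (stratified by label) for early stopping
  valIdx <- integer()
  if (hp$earlyStopPatience > 0L && hp$validationFraction > 0) {
    for (cl in c(0L, 1L)) {
      idx <- which(y == cl)
      k <- max(1L, round(hp$validationFraction * length(idx)))
      if (k < length(idx))
        valIdx <- c(valIdx, sample(idx, k))
    }
  }
  trIdx <- setdiff(seq_len(n), valIdx)
  Xt <- Matrix::t(X[trIdx, , drop = FALSE])   # features x entries: fast
  ytr <- y[trIdx]                             # column slicing per batch
  Xval <- if (length(valIdx)) X[valIdx, , drop = FALSE] else NULL
  yval <- y[valIdx]

  sizes <- c(ncol(X), hp$hiddenLayerSizes, 1L)
  L <- length(sizes) - 1L
  layers <- lapply(seq_len(L), function(l) {
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L]) *
                      sqrt(2 / sizes[l]), sizes[l], sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
  adam <- lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  nt <- length(trIdx)
  bs <- min(hp$batchSize, nt)
  best <- -Inf
  bestLayers <- layers
  wait <- 0L
  history <- vector("list", hp$maxEpochs)
  epochsRun <- 0L

  for (epoch in seq_len(hp$maxEpochs)) {
    perm <- sample.int(nt)
    starts <- seq(1L, nt, by = bs)
    epochLoss <- 0
    for (s in starts) {
      bidx <- perm[s:min(s + bs - 1L, nt)]
      nb <- length(bidx)
      Xb <- Matrix::t(Xt[, bidx, drop = FALSE])
      if (hp$inputDropout > 0) {
        keep <- stats::runif(length(Xb@x)) >= hp$inputDropout
        Xb@x <- Xb@x * keep / (1 - hp$inputDropout)
      }
      yb <- ytr[bidx]
      fw <- .mlpForward(layers, Xb, dropout = hp$dropout, training = TRUE,
                        cache = TRUE)
      p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
      epochLoss <- epochLoss - sum(yb * log(p) + (1 - yb) * log(1 - p))
      ## backprop: BCE with sigmoid output
      delta <- matrix((fw$p - yb) / nb, nb, 1L)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        dW <- as.matrix(Matrix::crossprod(fw$As[[l]], delta))
        db <- colSums(delta)
        if (l > 1L) {
          dA <- delta %*% t(layers[[l]]$W)
          dA <- dA * (fw$Zs[[l - 1L]] > 0)
          if (!is.null(fw$Ms[[l - 1L]])) dA <- dA * fw$Ms[[l - 1L]]
          delta <- dA
        }
        ## Adam update
        a <- adam[[l]]
        a$mW <- b1 * a$mW + (1 - b1) * dW
        a$vW <- b2 * a$vW + (1 - b2) * dW^2
        a$mb <- b1 * a$mb + (1 - b1) * db
        a$vb <- b2 * a$vb + (1 - b2) * db^2
        corr1 <- 1 - b1^step
        corr2 <- 1 - b2^step
        layers[[l]]$W <- layers[[l]]$W -
          hp$learningRate * ((a$mW / corr1) / (sqrt(a$vW / corr2) + eps) +
                               hp$weightDecay * layers[[l]]$W)
        layers[[l]]$b <- layers[[l]]$b -
          hp$learningRate * (a$mb / corr1) / (sqrt(a$vb / corr2) + eps)
        adam[[l]] <- a
      }
    }
    epochsRun <- epoch
    valMcc <- NA_real_
    if (!is.null(Xval)) {
      vp <- .mlpForward(layers, Xval)
      valMcc <- .mccValue(sum(vp >= 0.5 & yval == 1L),
                          sum(vp < 0.5 & yval == 0L),
                          sum(vp >= 0.5 & yval == 0L),
                          sum(vp < 0.5 & yval == 1L))
      if (valMcc > best + 1e-9) {
        best <- valMcc
        bestLayers <- layers
        wait <- 0L
      } else if (epoch > (hp$minEpochs %||% 0L)) {
        wait <- wait + 1L
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch,
                                   trainLoss = epochLoss / nt,
                                   valMcc = valMcc)
    if (!is.null(Xval) && wait > hp$earlyStopPatience) break
  }
  if (is.null(Xval)) bestLayers <- layers

  methods::new("MLPClassifier",
               layers = bestLayers,
               hp = unclass(hp),
               featureNames = colnames(X),
               history = do.call(rbind, history[seq_len(epochsRun)]),
               epochsRun = epochsRun)
}

#' @describeIn trainClassifier Train on the entries of a paired dataset.
#' @export
setMethod("trainClassifier", "PairedDataset", function(x, hp, ...) {
  .mlpTrain(features(x), entryLabels(x), hp)
})

#' @describeIn trainClassifier Train on a sparse feature matrix with an
#'   explicit `labels` vector.
#' @export
setMethod("trainClassifier", "dgCMatrix", function(x, hp, ..., labels) {
  .mlpTrain(x, labels, hp)
})

#' @describeIn trainClassifier Train on a dense matrix (converted to
#'   sparse) with an explicit `labels` vector.
#' @export
setMethod("trainClassifier", "matrix", function(x, hp, ..., labels) {
  .mlpTrain(methods::as(x, "CsparseMatrix"), labels, hp)
})

.alignColumns <- function(X, contract) {
  nm <- colnames(X)
  if (is.null(nm) || !setequal(nm, contract) || length(nm) != length(contract))
    .stopf("metpairs_model_error",
           "feature column contract mismatch: model expects %d columns",
           length(contract))
  if (identical(nm, contract)) X else X[, match(contract, nm), drop = FALSE]
}

#' Predict membership probabilities for paired entries
#'
#' Columns of the input are aligned to the model's feature-name contract
#' (permutation-safe); any difference in the column set is an error. The
#' hard label is `probability >= 0.5`.
#'
#' @param object An [MLPClassifier-class].
#' @param newdata A [PairedDataset-class] or a (sparse) feature matrix with
#'   named columns.
#' @param ... Ignored.
#' @return `data.frame` with columns `probability` and `label`.
#' @export
setMethod("predict", "MLPClassifier", function(object, newdata, ...) {
  X <- if (methods::is(newdata, "PairedDataset")) features(newdata)
       else if (is.matrix(newdata)) methods::as(newdata, "CsparseMatrix")
       else newdata
  X <- .alignColumns(X, object@featureNames)
  p <- .mlpForward(object@layers, X)
  data.frame(probability = p, label = as.integer(p >= 0.5))
})

#' Checkpoint a trained classifier
#'
#' Writes the parameter state (flat TSV of weights) plus a JSON sidecar
#' carrying hyperparameters and the feature-name contract.
#'
#' @param clf An [MLPClassifier-class].
#' @param dir Checkpoint directory (`weights.tsv` + `model.json`).
#' @return `saveClassifier()` returns `dir` invisibly; `loadClassifier()`
#'   the restored [MLPClassifier-class].
#' @export
saveClassifier <- function(clf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (l in seq_along(clf@layers)) {
    W <- clf@layers[[l]]$W
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l, kind = "W",
      i = rep(seq_len(nrow(W)), ncol(W)),
      j = rep(seq_len(ncol(W)), each = nrow(W)),
      value = as.numeric(W))
    b <- clf@layers[[l]]$b
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l, kind = "b", i = seq_along(b), j = 1L, value = b)
  }
  .writeTSV(do.call(rbind, rows), file.path(dir, "weights.tsv"))
  .writeJSON(list(hp = clf@hp, featureNames = clf@featureNames,
                  epochsRun = clf@epochsRun),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(dir) {
  w <- .readTSV(file.path(dir, "weights.tsv"))
  meta <- .readJSON(file.path(dir, "model.json"))
  layers <- lapply(sort(unique(w$layer)), function(l) {
    Wd <- w[w$layer == l & w$kind == "W", ]
    bd <- w[w$layer == l & w$kind == "b", ]
    W <- matrix(0, max(Wd$i), max(Wd$j))
    W[cbind(Wd$i, Wd$j)] <- Wd$value
    list(W = W, b = bd$value[order(bd$i)])
  })
  methods::new("MLPClassifier", layers = layers,
               hp = as.list(meta$hp),
               featureNames = as.character(meta$featureNames),
               history = data.frame(),
               epochsRun = as.integer(meta$epochsRun))
}

#' Random-search hyperparameter tuning
#'
#' Seeded random search: each trial samples a configuration from the search
#' space, trains on an inner stratified split and scores the held-out MCC;
#' the best-scoring configuration is returned. Fully deterministic given
#' the seed.
#'
#' @param dataset A [PairedDataset-class].
#' @param nTrials Number of sampled configurations (>= 1).
#' @param searchSpace List with elements `hiddenLayerSizes` (list of integer
#'   vectors to choose among), `learningRate` (length-2 range, sampled
#'   log-uniformly), `dropout` (length-2 range) and `batchSize` (choices).
#' @param seed Integer seed.
#' @param baseHp Fixed fields (epochs, patience, ...) taken from this
#'   [mlpHyperparameters()] object.
#' @param innerFraction Held-out fraction of the inner split.
#' @return The selected `mlpHyperparameters` object, with attributes
#'   `trials` (a `data.frame` of all trials) for inspection.
#' @export
tuneHyperparameters <- function(dataset, nTrials = 10L,
                                searchSpace = list(), seed = 1L,
                                baseHp = mlpHyperparameters(),
                                innerFraction = 0.2) {
  if (nTrials < 1L)
    .stopf("metpairs_config_error", "nTrials must be >= 1")
  space <- list(hiddenLayerSizes = list(c(64L), c(128L, 64L),
                                        c(512L, 128L)),
                learningRate = c(1e-4, 1e-2),
                dropout = c(0, 0.5),
                batchSize = c(256L, 512L, 1024L))
  for (nm in names(searchSpace)) space[[nm]] <- searchSpace[[nm]]
  set.seed(seed)
  split <- stratifiedSplit(dataset, testFraction = innerFraction,
                           seed = seed, key = "label")
  train <- dataset[split$train]
  val <- dataset[split$test]
  yval <- entryLabels(val)
  best <- NULL
  bestMcc <- -Inf
  trials <- vector("list", nTrials)
  for (t in seq_len(nTrials)) {
    hidden <- space$hiddenLayerSizes[[
      sample.int(length(space$hiddenLayerSizes), 1L)]]
    lr <- 10^stats::runif(1, log10(space$learningRate[1]),
                          log10(space$learningRate[2]))
    dp <- stats::runif(1, space$dropout[1], space$dropout[2])
    bsz <- space$batchSize[sample.int(length(space$batchSize), 1L)]
    hp <- mlpHyperparameters(hiddenLayerSizes = hidden, learningRate = lr,
                             batchSize = bsz, maxEpochs = baseHp$maxEpochs,
                             earlyStopPatience = baseHp$earlyStopPatience,
                             dropout = dp,
                             validationFraction = baseHp$validationFraction,
                             seed = seed + t)
    clf <- trainClassifier(train, hp)
    pred <- predict(clf, val)
    mcc <- .mccValue(sum(pred$label == 1L & yval == 1L),
                     sum(pred$label == 0L & yval == 0L),
                     sum(pred$label == 1L & yval == 0L),
                     sum(pred$label == 0L & yval == 1L))
    trials[[t]] <- data.frame(trial = t,
                              hidden = paste(hidden, collapse = "x"),
                              learningRate = lr, dropout = dp,
                              batchSize = bsz, valMcc = mcc)
    if (mcc > bestMcc) {
      bestMcc <- mcc
      best <- hp
    }
  }
  attr(best, "trials") <- do.call(rbind, trials)
  best
}
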