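#' @include evaluation.R
NULL

#' Configuration of the synthetic molecule/pathway generator
#'
#' The generator emulates the statistical structure the pipeline is built
#' for: a corpus of small organic-like molecular graphs (element
#' frequencies dominated by carbon), a two-level pathway hierarchy in which
#' individual (L3) pathways group metabolites and category (L2) pathways
#' are unions of disjoint L3 subsets, right-skewed pathway sizes (truncated
#' log-normal, minimum 3 members), and a planted chemical signal: each L3
#' pathway owns a distinct heteroatom motif path that its members carry with
#' probability `signalStrength`, while non-carriers carry a uniformly
#' random decoy motif so that structure is uninformative at strength 0.
#'
#' @param nMetabolites Number of molecules; each belongs to exactly one L3
#'   pathway.
#' @param nPathwaysL3,nPathwaysL2 Pathway counts (L2 may be 0).
#' @param atomRange Inclusive range of heavy-atom counts per molecule
#'   (motif atoms included).
#' @param elementWeights Named sampling weights for element symbols.
#' @param motifLibrary List of motifs (see [defaultMotifLibrary()]);
#'   must contain at least `nPathwaysL3` motifs.
#' @param signalStrength Probability in \[0, 1\] that a member carries its
#'   pathway's motif.
#' @param signalMode `"uniform"`: the same strength for every pathway;
#'   `"size"`: strength scaled by `min(1, size/sizeRef)` so larger pathways
#'   carry stronger signal.
#' @param sizeRef Reference size for `signalMode = "size"`.
#' @param sizeLogSd Log-scale standard deviation of the log-normal pathway
#'   size distribution (right-skewed).
#' @param minPathwaySize Minimum L3 pathway size (default 3).
#' @param extraEdgeProb Per-atom probability of an extra (cycle-forming)
#'   edge beyond the random spanning tree.
#' @param doubleBondProb,tripleBondProb Bond-order probabilities.
#' @param seed Integer master seed; identical configuration and seed give a
#'   byte-identical corpus.
#' @return A validated list of class `"generatorConfig"`.
#' @export
generatorConfig <- function(nMetabolites = 500L,
                            nPathwaysL3 = 20L,
                            nPathwaysL2 = 4L,
                            atomRange = c(5L, 8L),
                            elementWeights = c(C = 0.65, N = 0.12,
                                               O = 0.18, S = 0.03,
                                               P = 0.02),
                            motifLibrary = NULL,
                            signalStrength = 1,
                            signalMode = c("uniform", "size"),
                            sizeRef = 15L,
                            sizeLogSd = 0.6,
                            minPathwaySize = 3L,
                            extraEdgeProb = 0.15,
                            doubleBondProb = 0.15,
                            tripleBondProb = 0.03,
                            seed = 1L) {
  signalMode <- match.arg(signalMode)
  .assertScalarNumber(nMetabolites, "nMetabolites", lower = 1)
  .assertScalarNumber(nPathwaysL3, "nPathwaysL3", lower = 1)
  .assertScalarNumber(nPathwaysL2, "nPathwaysL2", lower = 0)
  .assertScalarNumber(signalStrength, "signalStrength", lower = 0, upper = 1)
  .assertScalarNumber(minPathwaySize, "minPathwaySize", lower = 1)
  .assertScalarNumber(seed, "seed")
  if (length(atomRange) != 2L || atomRange[1] < 1L ||
      atomRange[2] < atomRange[1])
    .stopf("metpairs_config_error", "invalid atomRange")
  if (nMetabolites < nPathwaysL3 * minPathwaySize)
    .stopf("metpairs_config_error",
           "infeasible size distribution: %d metabolites < %d pathways x %d",
           nMetabolites, nPathwaysL3, minPathwaySize)
  motifLibrary <- motifLibrary %||% defaultMotifLibrary(nPathwaysL3)
  if (length(motifLibrary) < nPathwaysL3)
    .stopf("metpairs_config_error",
           "motif library smaller than nPathwaysL3")
  structure(list(nMetabolites = as.integer(nMetabolites),
                 nPathwaysL3 = as.integer(nPathwaysL3),
                 nPathwaysL2 = as.integer(nPathwaysL2),
                 atomRange = as.integer(atomRange),
                 elementWeights = elementWeights,
                 motifLibrary = motifLibrary,
                 signalStrength = signalStrength,
                 signalMode = signalMode,
                 sizeRef = as.integer(sizeRef),
                 sizeLogSd = sizeLogSd,
                 minPathwaySize = as.integer(minPathwaySize),
                 extraEdgeProb = extraEdgeProb,
                 doubleBondProb = doubleBondProb,
                 tripleBondProb = tripleBondProb,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Deterministic library of planted 3-atom motifs
#'
#' Motifs are labeled paths `e1 -o1- e2 -o2- e3` over heteroatom elements
#' and bond orders 1-3, enumerated in a fixed order, so that distinct
#' pathways receive chemically distinct substructures whose canonical atom
#' colors differ.
#'
#' @param n Number of motifs.
#' @param motifLength Atoms per motif path (default 4).
#' @return List of motifs, each `list(elements, orders)`.
#' @export
defaultMotifLibrary <- function(n, motifLength = 4L) {
  if (motifLength < 2L)
    .stopf("metpairs_config_error", "motifLength must be >= 2")
  els <- c("N", "O", "S", "P")
  args <- list()
  for (k in seq_len(motifLength)) {
    args[[paste0("e", k)]] <- els
    if (k < motifLength) args[[paste0("o", k)]] <- 1:3
  }
  grid <- do.call(expand.grid,
                  c(args, list(stringsAsFactors = FALSE)))
  if (n > nrow(grid))
    .stopf("metpairs_config_error",
           "at most %d distinct motifs available", nrow(grid))
  eCols <- paste0("e", seq_len(motifLength))
  oCols <- paste0("o", seq_len(motifLength - 1L))
  lapply(seq_len(n), function(k)
    list(elements = unlist(grid[k, eCols], use.names = FALSE),
         orders = unlist(grid[k, oCols], use.names = FALSE)))
}

.motifString <- function(m) {
  k <- length(m$elements)
  paste(as.vector(rbind(m$elements,
                        c(as.character(m$orders), "")))[seq_len(2 * k - 1)],
        collapse = "-")
}

#' Generate one random molecule, optionally embedding a motif
#'
#' Builds a connected random graph: a random spanning tree over base atoms
#' sampled from the configured element distribution, extra cycle-forming
#' edges, and bond orders drawn from the configured probabilities. A motif,
#' when given, is appended as a labeled path attached to a random base atom
#' by a single bond, so the parsed graph is guaranteed to contain the
#' motif's labeled subgraph. The result serializes to a valid V2000 molfile
#' that round-trips through [parseMolfile()].
#'
#' @param config A [generatorConfig()].
#' @param motif A motif from the config's library, or `NULL`.
#' @param seed Integer seed for this molecule.
#' @param id Metabolite identifier.
#' @return A [MolecularGraph-class].
#' @export
generateMolecule <- function(config, motif = NULL, seed = 1L,
                             id = "M0001") {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(seed)
  nTotal <- if (config$atomRange[1] == config$atomRange[2])
    config$atomRange[1]
  else sample(config$atomRange[1]:config$atomRange[2], 1L)
  nMotif <- if (is.null(motif)) 0L else length(motif$elements)
  if (nMotif >= nTotal)
    .stopf("metpairs_generator_error",
           "motif (%d atoms) larger than molecule (%d atoms)",
           nMotif, nTotal)
  nBase <- nTotal - nMotif
  els <- sample(names(config$elementWeights), nBase, replace = TRUE,
                prob = config$elementWeights)
  pOrder <- c(1 - config$doubleBondProb - config$tripleBondProb,
              config$doubleBondProb, config$tripleBondProb)
  drawOrder <- function(k) sample(1:3, k, replace = TRUE, prob = pOrder)
  bonds <- NULL
  if (nBase > 1L) {
    parent <- vapply(2:nBase, function(i) sample.int(i - 1L, 1L),
                     integer(1))
    bonds <- cbind(parent, 2:nBase, drawOrder(nBase - 1L))
    nExtra <- stats::rbinom(1L, nBase, config$extraEdgeProb)
    for (k in seq_len(nExtra)) {
      pair <- sample.int(nBase, 2L)
      key <- paste(pmin(bonds[, 1], bonds[, 2]),
                   pmax(bonds[, 1], bonds[, 2]))
      if (!paste(min(pair), max(pair)) %in% key)
        bonds <- rbind(bonds, c(pair[1], pair[2], drawOrder(1L)))
    }
  }
  if (!is.null(motif)) {
    k <- length(motif$elements)
    attach <- sample.int(nBase, 1L)
    first <- nBase + 1L
    els <- c(els, motif$elements)
    mb <- rbind(c(attach, first, 1L),
                cbind(first + seq_len(k - 1L) - 1L,
                      first + seq_len(k - 1L),
                      motif$orders))
    bonds <- rbind(bonds, mb)
  }
  MolecularGraph(id, els, bonds)
}

## Right-skewed L3 pathway sizes summing exactly to nMetabolites, each at
## least minPathwaySize. Largest-remainder allocation of log-normal weights,
## then rebalancing from the largest pathways to enforce the minimum.
.allocateSizes <- function(nMet, nPw, logSd, minSize) {
  w <- stats::rlnorm(nPw, meanlog = 0, sdlog = logSd)
  raw <- w / sum(w) * nMet
  sizes <- floor(raw)
  rem <- nMet - sum(sizes)
  if (rem > 0) {
    ord <- order(-(raw - sizes), sample.int(nPw))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  while (any(sizes < minSize)) {
    i <- which.min(sizes)
    j <- which.max(sizes)
    if (sizes[j] <= minSize)
      .stopf("metpairs_generator_error", "infeasible size distribution")
    sizes[i] <- sizes[i] + 1L
    sizes[j] <- sizes[j] - 1L
  }
  as.integer(sizes)
}

#' Generate a synthetic corpus: molecules, pathways and planted signal
#'
#' Draws L3 pathway sizes from the truncated log-normal distribution,
#' assigns every metabolite to exactly one L3 pathway, groups the L3
#' pathways into disjoint L2 categories whose memberships are the unions of
#' their children's, and generates one molecule per metabolite, embedding
#' the pathway's motif with the configured signal strength (a decoy motif
#' otherwise). When `dir` is given, writes `molfiles/<id>.mol`,
#' `membership.tsv` and a `manifest.json` recording every planted motif and
#' membership; reruns with the same configuration produce byte-identical
#' output.
#'
#' @param config A [generatorConfig()].
#' @param dir Optional output directory.
#' @return (Invisibly when writing) a list with elements `graphs` (named
#'   list of [MolecularGraph-class]), `membership` (`data.frame`),
#'   `pathways` (`data.frame` incl. planted motif and signal strength per
#'   pathway) and `manifest` (list).
#' @export
generateUniverse <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(config$seed)
  n3 <- config$nPathwaysL3
  nMet <- config$nMetabolites
  sizes <- .allocateSizes(nMet, n3, config$sizeLogSd,
                          config$minPathwaySize)
  l3Ids <- sprintf("L3_%03d", seq_len(n3))
  strength <- switch(config$signalMode,
    uniform = rep(config$signalStrength, n3),
    size = config$signalStrength * pmin(1, sizes / config$sizeRef))
  metIds <- sprintf("M%04d", seq_len(nMet))
  metPathway <- rep(seq_len(n3), sizes)
  carries <- stats::runif(nMet) < strength[metPathway]
  nMotif <- length(config$motifLibrary)
  motifIdx <- ifelse(carries, metPathway,
                     sample.int(nMotif, nMet, replace = TRUE))
  ## L2 categories: disjoint groups over a random permutation of L3 pathways
  l2Of <- rep(NA_integer_, n3)
  l2Ids <- character()
  if (config$nPathwaysL2 > 0L) {
    l2Ids <- sprintf("L2_%02d", seq_len(config$nPathwaysL2))
    l2Of[sample.int(n3)] <- rep_len(seq_len(config$nPathwaysL2), n3)
  }
  molSeeds <- sample.int(2^30, nMet)

  graphs <- vector("list", nMet)
  names(graphs) <- metIds
  for (i in seq_len(nMet)) {
    graphs[[i]] <- generateMolecule(
      config, motif = config$motifLibrary[[motifIdx[i]]],
      seed = molSeeds[i], id = metIds[i])
  }

  membership <- data.frame(pathway_id = l3Ids[metPathway],
                           level = "L3",
                           metabolite_id = metIds)
  if (config$nPathwaysL2 > 0L) {
    membership <- rbind(
      data.frame(pathway_id = l2Ids[l2Of[metPathway]],
                 level = "L2",
                 metabolite_id = metIds),
      membership)
  }
  membership <- membership[order(membership$level, membership$pathway_id,
                                 membership$metabolite_id,
                                 method = "radix"), , drop = FALSE]
  rownames(membership) <- NULL

  pathways <- data.frame(
    pathway_id = l3Ids,
    level = "L3",
    size_compounds = sizes,
    motif = vapply(config$motifLibrary[seq_len(n3)], .motifString,
                   character(1)),
    signal_strength = strength,
    parent_l2 = if (config$nPathwaysL2 > 0L) l2Ids[l2Of] else
      NA_character_)
  if (config$nPathwaysL2 > 0L) {
    l2Sizes <- vapply(seq_len(config$nPathwaysL2), function(g)
      sum(sizes[which(l2Of == g)]), integer(1))
    pathways <- rbind(pathways, data.frame(
      pathway_id = l2Ids, level = "L2", size_compounds = l2Sizes,
      motif = NA_character_, signal_strength = NA_real_,
      parent_l2 = NA_character_))
  }

  manifest <- list(
    generator = "metpairs synthetic corpus",
    seed = config$seed,
    nMetabolites = nMet,
    nPathwaysL3 = n3,
    nPathwaysL2 = config$nPathwaysL2,
    signalStrength = config$signalStrength,
    signalMode = config$signalMode,
    pathways = pathways,
    molecules = data.frame(metabolite_id = metIds,
                           l3_pathway = l3Ids[metPathway],
                           motif_index = motifIdx,
                           carries_signal = carries,
                           seed = molSeeds))

  if (!is.null(dir)) {
    molDir <- file.path(dir, "molfiles")
    dir.create(molDir, showWarnings = FALSE, recursive = TRUE)
    for (id in metIds)
      writeMolfile(graphs[[id]], file.path(molDir, paste0(id, ".mol")))
    .writeTSV(membership, file.path(dir, "membership.tsv"))
    .writeJSON(manifest, file.path(dir, "manifest.json"))
  }
  out <- list(graphs = graphs, membership = membership,
              pathways = pathways, manifest = manifest, config = config)
  if (is.null(dir)) out else invisible(out)
}
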