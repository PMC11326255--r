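---
title: "metpairs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metpairs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metpairs)
```

# The problem

Metabolic knowledgebases map metabolites to the pathways they participate
in, but those mappings are incomplete. `metpairs` implements a
structure-based predictor of metabolite–pathway association: given only a
metabolite's molecular graph and a chemical representation of each pathway,
a single binary classifier scores every (metabolite, pathway) combination.
The design targets two-level pathway hierarchies of the kind used by KEGG —
broad L2 pathway categories and granular L3 individual pathways — and
treats both uniformly: any collection of metabolites defines a "pathway"
feature vector, so one model serves every pathway at every level and new
pathways can be added without retraining one model per pathway.

# Featurization: atom coloring

Each molecule is parsed from an MDL V2000 molfile into a hydrogen-free
graph (`parseMolfile()`): explicit hydrogens and their bonds are removed,
remaining atoms are re-indexed, and bond orders 1–4 are kept verbatim
(order 4, aromatic, is treated as its own order — no kekulization or
aromaticity perception, so featurization is purely deterministic).
Charges, isotopes and stereo flags are ignored: the features are
substructure *counts*, and none of those annotations enter them.
Multi-component structures (salts) stay one graph. V3000 input is
rejected rather than mis-read.

`colorAtoms()` assigns every atom a *color* at increasing bond radii:

* radius 0: the element symbol;
* radius r: `element(order:neighborColor(r-1), ...)` with the
  neighbor sub-colors lexicographically sorted.

Sorting the sub-colors makes the identifier canonical — invariant under
any re-ordering of atom indices — which the test suite checks by
property (random graphs under random permutations). Expansion for an atom
stops at its eccentricity, the radius at which its bonded neighborhood
stops growing; the deepest radius over all atoms is the graph diameter.
One color is emitted per atom per radius, and the molecule's feature
vector is the multiset of emitted colors. Consequently the radius-0
counts always sum to the non-hydrogen atom count, a useful invariant.
No minimum-frequency pruning is applied to the color vocabulary; every
color seen in the corpus gets a column, ordered lexicographically under C
collation so the layout is platform-independent.

# Pathway features, normalization, cross join

A pathway's chemical representation is the element-wise **sum** of its
members' raw count vectors, with a bond count equal to the summed member
bond counts. The query metabolite of a positive pair is *not* excluded
from its pathway's sum. No exclusion rule exists in the upstream
formulation this package follows; we document it as a known optimistic
bias and discuss its measurable footprint under *Synthetic data* below.

Two normalizations are applied:

* **Softmax by bond count** (entry-wise): for an entity with bond count
  $B$ and non-zero counts $c_i$,
  $x_i = \exp(c_i/B) \big/ \sum_j \exp(c_j/B)$.
  The softmax runs over the entity's non-zero colors only: a dense
  softmax over the full vocabulary (tens of thousands of columns) would
  flatten every vector toward uniformity and destroy sparsity. Zero-bond
  (single-atom) entities use $B = 1$. The divide-then-softmax reading was
  chosen over softmax-then-rescale and is isolated in one function,
  `softmaxByBondCount()`.
* **Min/max scaling** (feature-wise, optional): $x' = (x - \min)/(\max -
  \min)$ with the minima/maxima fit on the *training split of each CV
  iteration only*, then applied to train and test; out-of-range test
  values clip to $[0,1]$ and constant columns map to 0, keeping the
  "every feature value ranges between 0 and 1" contract exact. Fitting
  on the full dataset is available (`minmaxScale(ds)`) for fidelity
  experiments, but the pipeline default avoids that leakage.

`crossJoin()` then pairs every metabolite with every pathway — exactly
$|M| \times |P|$ entries, each concatenating the two normalized vectors
under disjoint `met::` / `pw::` namespaces with label
$\mathbb{1}[\text{metabolite} \in \text{pathway}]$. The cross join is the
data-engineering heart of the method: it multiplies the number of
positive examples to a level where a single binary classifier can be
trained, instead of one starved model per pathway.

# The classifier

`trainClassifier()` fits a fully-connected network: ReLU hidden layers, a
sigmoid output, binary cross-entropy, mini-batch Adam, optional inverted
dropout on hidden units and on the input features, and optional decoupled
(AdamW-style) weight decay. Training streams row batches from the sparse
feature matrix, so memory scales with the batch, not the dataset. Early
stopping monitors the MCC of a stratified validation carve-out
(`validationFraction`); because a heavily imbalanced model predicts the
negative class exclusively for the first few epochs, validation MCC sits
at 0 for a while, and a `minEpochs` warm-up prevents the patience counter
from firing inside that plateau. The best-validation weights are
restored. Given a seed, training is exactly reproducible.

Input dropout deserves a note. Deep-radius colors are frequently unique
to a single molecule; a large network can exploit them to memorize
individual training pairs instead of learning the shared substructure
rule, which costs held-out recall on small pathways. Randomly dropping
input features during training (default 0.5 in the desk-scale
configuration) suppresses that memorization and measurably improves
held-out MCC.

Defaults for `mlpHyperparameters()` are two hidden layers (512, 128),
dropout 0.2, batch 1024, learning rate $10^{-3}$, patience 5 — a sensible
configuration for datasets in the $10^5$–$10^6$ entry range. The
package's own tests, the workflow default configuration and the
acceptance script use a lighter desk-scale configuration (one hidden
layer of 96, learning rate $3\times10^{-3}$, max 45 epochs, patience 10,
input dropout 0.5) sized for the synthetic corpora described below. `tuneHyperparameters()` offers seeded random search over the
space (selection by inner-validation MCC), standing in for a fuller
hyperparameter-optimization loop.

# Evaluation

Cross-validation is repeated random subsampling (Monte-Carlo CV): each
iteration draws a fresh stratified split with 10% of entries in the test
set, fits scaling on the training side, trains, and predicts the test
side. The stratification key is `(pathway_id, label)` so every pathway
contributes positives and negatives proportionally; the per-stratum test
counts come from largest-remainder apportionment of the rounded overall
test size, which keeps every stratum within one entry of the nominal
fraction while letting small strata reach the test set in a fraction of
iterations (seeded random tie-breaks). A `label`-only key is available
when strata are too small.

Five metrics are reported per iteration — accuracy, precision, recall,
F1, and the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{tp \cdot tn - fp \cdot fn}
  {\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}},$$

with any zero factor in the denominator giving the defined value 0 (the
"no correlation" convention; precision/recall/F1 likewise return 0 on
zero denominators). Because small pathways often have no positives in a
single test split, per-pathway quality is *not* computed per iteration;
instead the per-pathway confusion counts are summed across all
iterations and a single overall MCC per pathway is computed from the
summed matrix (`pathwayOverallMCC()`), which is scale-invariant and
side-steps the division-by-zero hazard. The same summation gives one
overall MCC per hierarchy level (`levelOverallMCC()`) and, since counts
are additive, everything reconciles exactly: global = sum over levels =
sum over pathways, per iteration and overall — asserted by tests over the
persisted result tables.

Two size analyses mirror the standard questions about pathway size:

* `sizeMccCorrelation()` — Spearman (regular scale) and Pearson
  (log10 scale) correlations between overall pathway MCC and both size
  metrics (member count; summed non-hydrogen atoms), with asymptotic
  p-values and no multiple-testing correction;
* `mccByMetricThreshold()` — overall MCC of the pathways at or above a
  size threshold (inclusive, "at least N members"), computed from the
  already-summed counts without retraining; and
  `trainingFilterSweep()` — the stronger experiment in which pathways
  below the threshold are removed from the *training universe*, the model
  is retrained per threshold, and the MCC is always reported on one fixed
  evaluation pathway set so thresholds are comparable.

# Synthetic data: what it emulates, and what it does not

`generateUniverse()` produces a self-contained study corpus with no
external downloads: molfiles, a membership TSV, and a ground-truth
manifest. Its statistical choices:

* **Molecules** are connected random graphs of 5–8 heavy atoms: a random
  spanning tree plus occasional cycle-forming edges; elements drawn with
  weights C 0.65, N 0.12, O 0.18, S 0.03, P 0.02 (an organic-like mix);
  bond orders mostly single (double 0.15, triple 0.03). Sizes are below
  typical real metabolites — a deliberate desk-scale choice: purely
  random graphs share almost no substructure, so larger random molecules
  inflate the color vocabulary far beyond the ratio seen in real corpora
  (roughly 2.6 feature columns per metabolite); keeping molecules small
  keeps that ratio, and the compute cost, in a realistic regime.
* **Pathways**: each L3 pathway's size is drawn from a truncated
  log-normal (right-skewed, minimum 3 members, log-sd 0.6) and every
  metabolite belongs to exactly one L3 pathway; L2 categories are unions
  of disjoint random subsets of L3 pathways, with membership inherited —
  mirroring a category/pathway hierarchy.
* **Planted signal**: each L3 pathway owns a distinct 4-atom heteroatom
  path motif (elements from N/O/S/P, orders 1–3), appended to a member's
  base graph with probability `signalStrength`; non-carriers receive a
  uniformly random decoy motif, so at strength 0 molecular structure
  carries no information about membership. `signalMode = "size"` scales
  the strength by `min(1, size/sizeRef)`, giving larger pathways cleaner
  signal — the regime used for size-correlation tests.

What the generator does **not** emulate: valence-correct chemistry, ring
systems and recurring scaffolds, real element/bond statistics, shared
substructure between unrelated molecules, multi-pathway membership, and
KEGG's empirical size distribution. Passing tests therefore demonstrate
that the pipeline recovers a planted, learnable chemical signal under
realistic bookkeeping — not that any particular accuracy will be attained
on real knowledgebase data.

One measurable artifact deserves mention: because a pathway's feature
vector includes its members — the query of a positive pair among them —
an overlap between a metabolite's colors and a pathway's colors leaks a
little label information. Under the default protocol (early stopping on
validation MCC from the first epoch) the no-signal null stays near MCC 0
at the package's canonical corpus scale: the overlap signal is weak and
slow to emerge, and training stops in the initial plateau before
exploiting it. Forcing long training (a large `minEpochs`) lets the
model learn the overlap even with no planted signal — MCC ≈ 0.3 at
canonical scale, and 0.3–0.4 on very small corpora. The property tests
are sized and configured accordingly, and the bias is inherited by
design from the formulation this package follows rather than silently
"fixed".

# Numerical and bookkeeping choices

* Softmax is computed as `exp(s - max(s))/sum(...)` for stability.
* MCC uses double precision throughout (counts up to $10^6$ square
  safely) and the zero-denominator → 0 convention uniformly.
* Min/max scaling preserves sparsity: all features are non-negative, so
  implicit zeros map to 0 under clipping even when a column's fitted
  minimum is positive.
* Vocabulary order, membership tables and persisted TSV/JSON output are
  sorted under C collation; identical configuration and seeds produce
  byte-identical corpora and result stores (asserted by md5 in tests).
* Per-iteration seeds are `baseSeed + iteration`; every random stage
  (split, initialization, batch order, dropout) derives from them.
* Persistence uses plain-text formats: MatrixMarket for sparse features,
  TSV for tables, JSON for manifests and model sidecars.

# Problem sizes used by the tests

The packaged checks run, as the package's own choice of study size: a
500-metabolite corpus with 20 L3 + 4 L2 pathways (12,000 cross-join
entries) for signal-recovery checks over 10 CV iterations; a
400-metabolite, 50 L3 + 5 L2 corpus with size-dependent signal for the
size-correlation analysis; a 300-metabolite corpus for the
signal-monotonicity property; and ~90-metabolite corpora for the
end-to-end workflow and determinism checks. The published set sizes
(5,683 metabolites; 12/172/184 pathways) are exercised analytically
through the cross-join cardinality check on a mock feature store.

# Known limitations

* The atom-coloring radius schedule and duplicate-emission policy are a
  defensible, deterministic reading of circular-substructure coloring;
  other implementations may emit stabilized colors differently. The
  choice is isolated behind `colorAtoms()`.
* The self-inclusion bias discussed above.
* Min/max scaling's fit scope (train-only versus global) is a
  pipeline-level decision; train-only is the default here.
* The MLP is CPU-only; large corpora are supported through sparse
  batched training but will be slow compared to GPU implementations.
* `tuneHyperparameters()` is plain random search — adequate for small
  spaces, not a substitute for a modern pruning-based tuner.
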