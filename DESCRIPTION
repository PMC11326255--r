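Package: metpairs
Title: Metabolite-Pathway Association Prediction from Atom-Coloring
    Features with a Single Cross-Join Classifier
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the association of metabolites with metabolic
    pathways (e.g. KEGG level-2 pathway categories and level-3 individual
    pathways) from chemical structure alone. Metabolites are parsed from
    MDL V2000 molfiles into hydrogen-free molecular graphs and featurized
    with an atom-coloring technique that counts canonical circular
    substructure identifiers at increasing bond radii. Pathways are
    represented chemically by summing the count vectors of their member
    metabolites. Every metabolite is cross-joined with every pathway to
    produce one labeled entry per pair, so that a single binary
    multi-layer perceptron classifier can predict membership for an
    arbitrary (metabolite, pathway) combination. Includes softmax-by-bond
    -count and min/max normalization, Monte-Carlo cross-validation with
    stratified splits, per-pathway confusion-count aggregation into
    overall Matthews correlation coefficients, pathway-size correlation
    and threshold-sweep analyses, and a synthetic molecule/pathway
    generator with planted substructure signal for end-to-end testing
    without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'molfile-io.R'
    'atom-coloring.R'
    'dataset.R'
    'mlp.R'
    'evaluation.R'
    'synthetic.R'
    'cli.R'
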