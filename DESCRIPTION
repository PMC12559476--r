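Package: t3pkskit
Title: Kingdom-Wide Characterisation Toolkit for Type III Polyketide Synthases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Mining, clustering and substrate-specificity modelling of type III
    polyketide synthases (T3PKS). Detects candidate enzymes in protein
    collections by local-alignment similarity to seed queries, builds sequence
    similarity networks with representative-node collapsing and identity-cutoff
    clustering, maps active-site residues onto chalcone-synthase reference
    numbering (catalytic Cys-His-Asn triad and substrate-pocket positions),
    featurises enzymes by mean-pooled per-residue descriptors and substrates by
    MACCS-key or circular (Morgan/ECFP) fingerprints, and trains seed-repeated
    binary enzyme-substrate activity classifiers (decision tree, random forest,
    multilayer perceptron) evaluated by repeated stratified cross-validation
    and deployed as seed-averaged prediction matrices. Includes a descriptive
    per-position importance model, a synthetic-data generator for homologous
    protein families with planted motif-by-substructure activity rules, and a
    deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    igraph,
    ChemmineR,
    ChemmineOB,
    ranger,
    rpart,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'active-site.R'
    'alignment.R'
    'embedders.R'
    'featurize.R'
    'fingerprints.R'
    'importance.R'
    'io.R'
    'methods-accessors.R'
    'mining.R'
    'model.R'
    'pipeline.R'
    'ssn.R'
    'synthetic.R'
    'zzz.R'
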