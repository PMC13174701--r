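Package: lintrace
Title: Lineage-Recorder Tree Reconstruction and Fate-Restriction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for CRISPR/prime-editing lineage recorders in
    developing embryos. Provides a ground-truth simulator for edited lineage
    cassettes (pure-birth division trees, irreversible per-site exponential
    editing, heritable cassette silencing, capture subsampling, ambient and
    doublet noise), quality-control filters for allele tables with adaptive
    Gaussian-mixture thresholds, scalable character-matrix tree reconstruction
    (greedy high-confidence splits plus neighbor joining on a custom edit
    distance with outgroup rooting), Sankoff ancestral state reconstruction
    with maximum-likelihood branch-length dating under an exponential editing
    model, and a suite of clonal fate-restriction statistics: entropy-based
    fate bias with permutation nulls, fate-restricted clades and their timing,
    sibling outputs, ancestral linkage, clade co-occurrence, bipotency,
    heritability, transcriptional divergence, proliferation scores, and
    lineage-kernel gene-program detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    data.table,
    igraph,
    mclust,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
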