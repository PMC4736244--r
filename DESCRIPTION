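Package: phenodiff
Title: Phenotype-Driven Differential Disease Ranking and Transitive Variant
    Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ontology-based semantic similarity between patient phenotype
    term sets and a catalog of Mendelian diseases, with transitive
    prioritization of candidate genes and variants through ranked disease
    intermediates.  Implements symmetrized Resnik similarity, ancestral
    term overlap (ATO) and its information-content and topologically
    weighted variants; inheritance-model and curation filters; classical
    multidimensional-scaling disease maps with query projection and radar
    (polar) layouts; phenotype suggestion; and protein-interaction-network
    driven disease gene discovery.  Ships seeded synthetic generators for
    every input format (OBO ontology, disease annotations, gene maps, VCF,
    PPI edge lists) so the full pipeline can be exercised without external
    downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
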