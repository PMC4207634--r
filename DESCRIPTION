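Package: lepihox
Title: Homeobox Discovery and Molecular Evolution in Draft Lepidopteran Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and characterising divergent
    homeobox genes (such as the lepidopteran Shx family) in low-coverage draft
    genome data. Provides k-mer-spectrum genome-size estimation from shotgun
    reads, six-frame profile search and classification of homeodomains in
    assembly contigs, lineage-aware conserved-motif detection and invariant-site
    statistics for protein alignments, counting-based dN/dS contrasts
    (Nei-Gojobori 1986), and an in silico mutation/selection engine that evolves
    preferred DNA binding sites for homeodomains against a pluggable
    protein-DNA energy model. A synthetic-data module generates every input
    with known ground truth so the whole pipeline can be exercised and
    validated without large sequencing datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
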