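Package: regenscreen
Title: Comparative Genomic Screen for Genes Conserved in Highly Regenerative Metazoans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phylogenetic-profiling pipeline that identifies gene families
    conserved across whole-body-regenerating (WBR) Cnidaria and Bilateria and
    lost in species with low regenerative ability (LRA). Provides an exact
    Smith-Waterman similarity engine with Karlin-Altschul E-values and
    mutual-best-hit orthology calling, orthogroup construction and loss
    filtering with a confirmation panel, distance-based gene trees with
    bootstrap supports for ortholog/paralog adjudication, JASPAR position
    weight matrix scanning with Fisher-exact target-versus-background
    enrichment over nested promoter windows, rule-based classification of
    amputation time-course expression profiles, qPCR relative quantification,
    and a synthetic-data generator that plants ground-truth gene families,
    promoter motifs and expression phases so every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pheatmap,
    optparse
Config/testthat/edition: 3
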