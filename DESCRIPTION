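Package: plastannot
Title: Reference-Guided Annotation and Analysis of Plastid Genomes
Version: 0.1.0
Authors@R: person("plastannot", "developers", role = c("aut", "cre"),
    email = "plastannot@example.org")
Description: Annotates plastome (chloroplast genome) sequences against
    user-supplied GenBank references. Implements anchored micro-exon
    detection for petB, petD and rpl16 using conserved 50-bp UTR
    sequences, assembly of the trans-spliced rps12 gene from
    individually located exons, reconciliation of tRNA predictions
    from two external predictors, discovery of SSR, tandem and
    dispersed repeats, and exploratory SNP and C-to-U RNA-editing
    site calling from aligned reads. Emits GFF3, GenBank flat files,
    NCBI five-column feature tables and an SVG circular map, and
    ships a deterministic synthetic-plastome simulator used as the
    test substrate.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
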