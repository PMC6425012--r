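Package: capv2g
Title: Variant-to-Gene Mapping with Promoter Capture C and ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physical variant-to-gene mapping for GWAS loci by intersecting
    linkage-disequilibrium proxy variants with ATAC-seq open chromatin and
    promoter-focused Capture C chromatin interactions. Provides in-silico
    restriction digestion and promoter bait design for 4-cutter capture
    designs, dual-resolution (1-fragment and 4-fragment) interaction merging,
    promoter-interactome summary statistics, distance-matched permutation
    enrichment of promoter-interacting regions, locus classification relative
    to the nearest gene, and a synthetic-study generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
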