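Package: PlastomeAuth
Title: Comparative Plastome Structure Analysis and Species-Authentication
    Barcode Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular chloroplast
    genomes and 45S ribosomal DNA cistron units from closely related plant
    species. Detects the inverted-repeat pair and quadripartite partition of a
    plastome and boundary (junction) shifts between genomes; builds collinear
    anchor chains and calls SNPs, indels and segmental inversions at the
    intra- and interspecies level; catalogs tandem-repeat copy-number
    variation; screens protein-coding genes for selection with Nei-Gojobori
    (1986) Ka/Ks estimates; and designs and validates in silico PCR assays
    (size-polymorphic pairs, three-primer junction assays and allele-specific
    primers) that discriminate species. A seeded simulator of three-taxon
    genome trios with planted structural events provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
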