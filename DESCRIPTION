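Package: idcqtl
Title: GWAS and QTL Discovery for Iron Deficiency Chlorosis in Soybean
    Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end association-mapping pipeline for visually scored
    iron deficiency chlorosis (IDC) in advanced soybean breeding lines:
    genotype input and minor-allele-frequency filtering, least-squares-mean
    phenotype adjustment across populations, principal-component and
    centered-relatedness control of population structure, exact
    mixed-linear-model single-marker tests with rank-based model selection,
    bootstrap empirical percentile significance thresholds, partial-r2
    linkage disequilibrium and decay-curve fitting, stepwise marker
    selection, LD-chained QTL-region delineation with block merging and
    candidate-gene overlap, all-pairs epistasis scanning, codon-level
    variant-effect annotation, and allelic-combination tolerance
    classification for marker-assisted selection.  A seeded breeding-
    population simulator with planted additive QTL supports calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
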