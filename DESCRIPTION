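Package: dmrdyn
Title: RRBS Differential Methylation Regions and Their Recovery Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-cascade calling of differentially methylated regions
    (DMRs) from reduced representation bisulfite sequencing (RRBS) coverage
    data, classification of DMR dynamics across post-exposure recovery
    timepoints (shared, recovered, new), CpG-density and replicate-variation
    profiling, and the associated overlap and concordance statistics
    (length-preserving interval-shuffle permutation enrichment,
    hypergeometric set overlap, delta-methylation correlation). Includes a
    beta-binomial synthetic methylome generator with a ground-truth ledger,
    negative-binomial expression simulation with dispersion inflation, and
    reader/writers for Bismark-dialect cytosine coverage files and BED.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
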