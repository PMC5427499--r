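Package: cnvdiv
Title: Windowed Copy-Number Variant Calling and Population CN Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Read-depth copy-number analysis for multi-strain yeast cohorts:
    GC-corrected, median-normalized windowed copy-number estimation, run-based
    segmentation into copy-number variable regions (CNVRs) with rank-sum
    significance filtering, genic copy number by window-overlap averaging,
    per-locus copy-number diversity scoring with log10 variance and polymorphic
    information content (PIC), percentile-based selection of CN-diverse loci,
    and subtelomeric/pericentromeric context analysis. Includes a synthetic
    multi-strain depth simulator with ground-truth duplication/deletion events
    for parameter-recovery benchmarking, and a reproducible end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
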