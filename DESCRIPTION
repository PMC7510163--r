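Package: strandcc
Title: Strand Cross-Correlation Quality Control for ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peak-call-independent quality control for ChIP-seq experiments based
    on strand cross-correlation of binarised read-start densities. Computes naive
    (NCC) and mappability-sensitive (MSCC) cross-correlation profiles from aligned
    reads, merges chromosomes by Fisher's r-to-z transformation, and derives QC
    metrics: fragment length, enriched-region width (FWHM), the virtual
    signal-to-noise ratio VSN, NSC and RSC. A generative read-density model
    provides closed-form expected coefficients and theoretical maxima/minima in
    the unsaturated and saturated regimes, a simulator generates synthetic
    alignments exactly under that model, and a cohort workflow predicts expected
    signal-to-noise and peak numbers for new samples from their VSN.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
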