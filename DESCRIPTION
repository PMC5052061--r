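Package: endscan
Title: Quantification of RNA 3'/5' End-Sequencing Data with
    Scan-Statistic Window Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying digital gene expression libraries that
    sequence transcript 3' or 5' ends. Reads aligned to a genome are
    reduced to strand-aware counting positions, assigned to union
    ("metatranscript") gene models with optional extension past the
    annotated transcript end, and scanned with fixed-length windows whose
    significance is assessed with a scan-statistic p-value conditional on
    the gene expression level. Includes four multimapped-read policies
    (including two-pass unique-locus rescue), low-complexity poly(A)/(T)
    read filtering, single-cell barcode/UMI preprocessing with PCR
    duplicate removal and knee-based cell calling, a global differential
    end-usage (alternative polyadenylation shift) test, and a synthetic
    aligned-read simulator with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
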