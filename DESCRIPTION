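Package: pmlseq
Title: Tumor-Only Somatic Mutation and Copy-Number Post-Processing for
    FFPE Pre-Malignant Lesion Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing stack for tumor-only targeted sequencing of
    formalin-fixed (FFPE) pre-malignant lesions: two-caller ensemble
    intersection, panel-of-normals subtraction, population-germline
    filtering with cancer-gene rescue, heuristic artifact filter profiles
    tuned for FFPE deamination damage, copy-number burden, chromosome-arm,
    gene-level and LOH calls from CNVkit-style bins and segments,
    multi-region mutation presence classification under a Bayesian
    read-count model, clone-tree construction, precision/recall
    benchmarking against a truth set, and a seeded synthetic-cohort
    generator with known ground truth so the full cascade is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
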