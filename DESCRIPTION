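Package: episig
Title: Discovery, Validation and Comparison of DNA Methylation Episignatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for deriving blood DNA-methylation
    episignatures of genetic disorders from EPIC-like beta-value matrices:
    probe filtering, reference-based leukocyte deconvolution, matched-control
    selection, moderated differential-methylation testing with
    empirical-Bayes variance shrinkage and Benjamini-Hochberg control,
    correlation-pruned probe-set selection scored by case/control
    separation, a calibrated support-vector-machine classifier producing
    methylation-variant-pathogenicity (MVP) scores, CpG-island and gene
    context annotation with differentially-methylated-region detection, and
    cross-cohort signature overlap and relatedness analyses. A synthetic
    EPIC-like cohort generator with planted signatures provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    e1071,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
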