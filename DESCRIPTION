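Package: txrecover
Title: Quantifying UV-Induced RNA Polymerase II Repositioning and
    Transcription Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for promoter-proximal pausing and
    transcription-recovery genomics. Computes traveling ratios (pausing
    indices) and replicate-consistent shift classifications from ChIP-seq
    fragment coverage, TSS-anchored metaprofiles with input subtraction and
    area-under-curve normalization, Ub-H2B gene-body profiles scaled to
    imaging-derived global levels, nascent-RNA (BrU-seq) bin-RPKM recovery
    profiles with damage-density decay fits, and a Perseus-style label-free
    proteomics enrichment workflow (downshifted imputation, two-sided
    t-test volcano, SILAC ratio enrichment, iBAQ stoichiometry). Includes
    a synthetic-data generator emulating pause, release and elongation
    structure so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
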