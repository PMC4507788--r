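Package: hlaswath
Title: HLA Immunopeptidome Annotation and SWATH-MS Assay Library Generation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for digital immunopeptidome analysis: automated annotation of
    identified HLA class I peptides to their presenting allele via a
    binding-affinity ratio score, target-decoy false discovery rate estimation
    with an annotation-corrected FDR, construction of HLA allele-specific
    consensus spectral libraries, iRT retention-time normalization, selection of
    fragment-ion transitions into OpenSWATH-style assay libraries with decoy
    assays, and generation of DIA/SWATH precursor isolation-window schemes. A
    synthetic-fixtures module (motif-based mock binding predictor,
    identification tables with decoys, fragment spectra with iRT landmarks)
    provides fully self-contained, seed-deterministic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
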