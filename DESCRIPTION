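Package: brafsig
Title: Nearest-Centroid Gene Signature Scoring and FFPE Translation for
    the BRAF-Mutation-Like Colorectal Cancer Subtype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for running a two-class nearest-centroid gene-expression
    classifier -- the 58-gene BRAF-mutation-like signature for colorectal
    cancer -- and for translating it from fresh-frozen tissue to
    formalin-fixed, paraffin-embedded (FFPE) samples. Covers centroid
    template construction, correlation-difference signature scoring,
    leave-one-out cross-validation with threshold selection at optimal
    overall accuracy, pre-screen enrichment accounting, technical-control
    stability QC against the signature score range, borderline-region
    definition, and paired fresh-frozen/FFPE concordance analysis. A
    synthetic-cohort generator with an FFPE degradation channel makes the
    whole workflow testable without access to microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
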