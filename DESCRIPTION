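Package: coumascreen
Title: Diagnostic-Ion Screening and Molecular Networking for Coumarins
    and Cinnamic Acids in Untargeted LC-MS/MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotation workflow for positive-mode untargeted LC-MS/MS
    metabolomics of coumarins and cinnamic acids. Implements elemental
    formula and monoisotopic mass arithmetic, MGF spectrum and feature
    table input, in-house compound library construction and precursor
    matching, in-silico neutral-loss fragment ladders with
    diagnostic-ion scoring, automatic class and modification screening
    with tier assignment, coumarin-dimer linkage discrimination,
    feature-based molecular networking with the modified cosine score,
    PLS-DA/VIP and volcano differential-feature selection, coverage
    reporting against the coumarin biosynthetic pathway, and seeded
    synthetic-data generators for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
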