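Package: famregion
Title: Family- and Population-Based Region Association Tests for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based (gene-set) association testing for quantitative
    traits under both family-based and population-based designs. Implements
    the FBAT family of region tests (burden, multimarker, linear-combination
    and variance-component permutation tests) with model-based and empirical
    variance estimators for extended pedigrees, a weighted-kernel score test
    and a region-restricted variance-component REML likelihood-ratio test for
    unrelated individuals, functional variant prioritization, phenotype
    residualization, a gene-window chromosome scan, and a gene-dropping
    pedigree simulator with a type-I-error / power evaluation harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    MASS,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
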