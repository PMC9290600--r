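Package: cbcsim
Title: Simulation and Validation of an Image-Based Complete Blood Count Analyzer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the image-analysis and
    statistical-validation machinery behind microscopy-based complete blood
    count (CBC) analyzers. Provides a synthetic multispectral blood-monolayer
    simulator (five brightfield/fluorescence channels with ground truth),
    red-cell, white-cell and platelet analysis pipelines, a multi-wavelength
    unlysed hemoglobin photometry model, compilation of a 19-parameter
    five-part-differential CBC with abnormality flags and validity rules, and
    the CLSI-style validation statistics used to qualify such devices:
    Passing-Bablok method comparison, median-of-differences bias, pooled-SD
    repeatability, nested reproducibility variance components, exact binomial
    (Clopper-Pearson) agreement intervals and Ruemke two-examiner differential
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
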