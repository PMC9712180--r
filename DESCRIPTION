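Package: xlung
Title: Cross-Domain Lung CT Radiomics: Extraction, Stability and Model Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative CT analysis of interstitial lung disease
    (ILD) across acquisition domains. Implements IBSI-style extraction of a
    154-feature histogram and texture signature (GLCM, GLRLM, GLSZM, GLDZM,
    NGLDM, NGTDM) from Hounsfield-unit volumes with lung masks, including
    isotropic resampling, HU re-segmentation, fixed-bin-size discretization
    and dual (averaged/merged) directional aggregation; delineation-stability
    filtering by two-way consistency intraclass correlation; per-feature
    directional AUC screening with cross-domain correlation; and MEAN, MSSK
    and machine-learning classifiers with nested cross-validated feature
    selection, domain transfer testing, target-domain re-optimization and
    Youden-cutoff diagnostics with bootstrap confidence intervals. Ships a
    two-domain lung phantom simulator (microCT-like and HRCT-like) with
    observer-perturbed masks so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    glmnet,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
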