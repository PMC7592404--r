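Package: lungtexture
Title: Apical Lung CT Density and GLCM Entropy Mapping for Radiotherapy Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies apical lung parenchyma on radiotherapy planning CT.
    Extracts a cylindrical volume of interest, quantises grey levels into 16
    fixed bins derived from a reference patient, computes a voxel-wise
    grey-level co-occurrence matrix (GLCM) entropy map over the 26-voxel
    neighbourhood, reduces density and entropy to per-patient summary
    features, and compares fit versus unfit cohorts (FEV1/TLCO 50%-predicted
    rule) with two-sided Mann-Whitney tests and Spearman correlations. A
    synthetic phantom module generates emphysema-like cohorts so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
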