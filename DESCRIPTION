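Package: cvdecode
Title: Decoding Cardiovascular Risk from Structural Gray-Matter Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate pattern analysis linking structural gray-matter
    probability maps to the Framingham coronary heart disease risk score.
    Provides linear-kernel support vector classification and
    epsilon-insensitive support vector regression on precomputed kernels,
    kernel-level confound removal through a residual-forming matrix,
    gender- and age-matched leave-pair-out cross-validation, permutation
    significance testing, single risk-factor regression batteries with
    gender and APOE4 subgroup splits, voxel weight-map back-projection,
    and a synthetic cohort generator so the full pipeline can be
    exercised and validated end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    MASS,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
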