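Package: lymphmap
Title: MRI-Based Tissue Composition Analysis of Lymphoedematous Arms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated post-processing of co-registered Dixon-water, Dixon-fat and
    STIR magnetic resonance volumes of the arm for breast cancer-related
    lymphoedema assessment. Segments muscle, fat and fluid by k-means clustering
    in the three-channel intensity feature space, separates the epifascial from
    the subfascial compartment by automatic contouring of the arm surface and the
    muscle fascia, quantifies six tissue volumes per arm by voxel counting, and
    builds longitudinal and radial excess-volume maps for affected/unaffected arm
    pairs together with cohort-level statistics. Includes a synthetic arm phantom
    generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
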