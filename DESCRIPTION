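Package: bonemicro
Title: Quantitative CT Assessment of Peripheral Bone Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cortical and trabecular bone microstructure from
    volumetric CT images of the distal tibia. Provides phantom-based
    Hounsfield-to-density calibration, windowed-sinc isotropic resampling,
    anatomy-standardized region-of-interest selection (end-plateau detection,
    tibial-axis realignment, percent-site and percent-peel regions), fuzzy
    skeletonization of the trabecular network, tensor-scale plate-width and
    orientation analysis, star-line thickness and separation, digital
    topological classification with erosion index, the structure model index,
    and cortical thickness and porosity. A companion statistics layer covers
    accuracy calibration against a reference modality, intraclass-correlation
    reproducibility, unadjusted and covariate-adjusted group comparisons with
    effect sizes, and exact two-sample t-test power. Synthetic phantom
    generators with analytic ground truth support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    emmeans,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
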