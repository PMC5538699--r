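Package: ventrecon
Title: Anatomically Informed EIT Reconstruction of Regional Lung Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing regional lung ventilation with thoracic
    electrical impedance tomography (EIT). Implements a complete-electrode-model
    finite-element forward solver on extruded 2.5D thorax meshes with a skip-4
    stimulation pattern, GREIT and one-step regularized Gauss-Newton image
    reconstruction with noise-figure-matched hyperparameters, tidal-image
    post-processing (time-difference and normalized-time-difference referencing,
    breath-phase detection, thresholding, lung masking), anteroposterior
    ventilation profiles, and the comparison statistics used to validate EIT
    against reference tidal aeration images (RMSE, pooled Pearson correlation,
    Bland-Altman with median bias and quantile limits, Kruskal-Wallis with
    rank-based post-hoc tests). A synthetic thorax-phantom generator simulates
    breathing-driven EIT recordings with ground-truth aeration images so that
    circular, averaged and individualized reconstruction geometries can be
    compared without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    deldir,
    polyclip,
    sp,
    stats,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
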