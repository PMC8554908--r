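Package: legvol
Title: Bilateral Leg Volumetry from Whole-Body 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies bilateral leg volume from single-capture whole-body 3D
    surface meshes. Provides triangle-mesh input/output (STL, PLY, OBJ),
    automatic alignment of the turntable support plane to the transverse
    origin plane, exact transverse-plane cropping between the infragluteal
    fold and the lateral malleolus, a limited-visibility workflow that splits
    fused legs at the median sagittal plane and closes the cut with flat-plane
    hole filling, spike-edge removal and small-hole filling, divergence-theorem
    volumetry in millilitres, and a repeated-scan precision analysis (relative
    percent differences, paired t-tests, rank-sum comparisons, WHO BMI
    subgroups). Ships a synthetic phantom generator with closed-form volumes
    so the entire workflow can be validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
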