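Package: olivescan
Title: Canopy Structure Phenotyping from Ground-Vehicle LiDAR and
    Multispectral Proximal Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct olive-tree canopies from side-mounted 2D
    line-scan LiDAR surveys and to quantify the structural change caused by
    pruning. Includes a parametric orchard simulator with a seeded ray-casting
    scan model and a proximal multispectral emulator, polar-to-Cartesian
    reconstruction with reference-marker side pairing, ground and trunk
    segmentation, the four canopy volume estimators used in mobile laser
    scanning studies (slice-wise convex hull, voxel occupancy, cylinder and
    sphere simplifications), point-density profiles along canopy height and
    thickness, vegetation-index computation and cleaning, and the associated
    correlation and pre/post-pruning comparison statistics.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
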