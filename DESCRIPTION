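Package: needleCT
Title: Needle Detection in Transverse CT Slices by Pretest-Accelerated
    Locally Optimised RANSAC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic detection of brachytherapy needles in 2D transverse
    CT slices. A candidate point cloud is obtained from a contour-derived
    region of interest by gamma contrast stretching and intensity
    thresholding; needle axes are then estimated with a robust line
    estimator that combines random sample consensus with a binomial
    pretest on small point subsets, local resampling of the consensus set,
    and a final total-least-squares (PCA) fit.  Needle tips are localised
    from the intensity profile along the fitted axis, and several needles
    per slice are extracted by successive deletion of each accepted
    needle's inliers.  A synthetic-data module generates planted-line
    point clouds and rendered needle-phantom slices with exact ground
    truth, so the whole pipeline can be exercised and benchmarked without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
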