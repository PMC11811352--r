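Package: cobb3d
Title: Three-Dimensional Cobb Angle Measurement from Spine Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing pipeline that turns a binary spinal-column
    segmentation mask (NIfTI) into three-dimensional Cobb angle estimates
    for scoliosis assessment. Spoke-kernel filtering strips transverse and
    spinous processes and severs narrow bridges between vertebrae; K-means
    clustering and least-squares cubic B-spline (NURBS) fitting extract a
    smooth spinal centerline; pairwise tangent-angle maps yield a 3D Cobb
    statistic and its coronal-projection counterpart. A synthetic scoliotic
    phantom generator with analytically known curvature supports end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
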