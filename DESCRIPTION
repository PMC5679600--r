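Package: crestmark
Title: Landmark Identification on Isosurfaces Extracted from Volumetric Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase functional pipeline that reduces a 3D scalar volume
    to a set of surface landmarks. Phase one extracts the isosurface as a
    triangle mesh with a continuation-based implicit-surface polygonizer over
    a tri-linearly interpolated field. Phase two computes principal curvatures
    from the volume (gradient and Hessian of the implicit function), estimates
    the gradient of the maximal principal curvature with a first-ring weighted
    estimator, and traces crest lines as zero-crossings of the extremality.
    Phase three thresholds crest points by Gaussian curvature, clusters the
    candidates with K-means (number of clusters chosen by the mean silhouette
    coefficient), and selects one landmark per cluster as the point of maximal
    curvedness. Includes a synthetic-data generator (spheres, ellipsoids,
    superellipsoids, tori) with closed-form curvature oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
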