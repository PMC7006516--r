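Package: footssm
Title: Statistical Shape Models of the Functional Bone Segments of the Foot
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate, and apply statistical shape models (point
    distribution models) of bone surface geometry, with tooling aimed at the
    four functional segments of the foot (first metatarsal, midfoot,
    calcaneus, talus). Provides STL and landmark-XML input/output, two-stage
    correspondence (radial-basis-function non-rigid warp followed by rigid
    iterative closest point), principal-component shape models with
    Mahalanobis-penalized reconstruction from full surfaces or three sparse
    anatomical landmarks, leave-one-out validation with volumetric Jaccard,
    surface RMSE and Hausdorff metrics, and a seeded synthetic bone-surface
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
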