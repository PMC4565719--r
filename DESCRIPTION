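Package: osteomech
Title: Volumetric Mass Properties, Joint Mobility and Retrodeformation for Digital Skeletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A geometry toolkit for skeleton-based biomechanics of fossil
    vertebrates. Builds lofted octagonal-hoop body outline models around a
    skeletal axis and computes segment and whole-body mass and centre of mass
    with min/max sensitivity envelopes; estimates maximal joint mobility by
    rotating a limb bone about an anatomical joint coordinate system at a
    sphere-fitted joint centre until bone-bone collision, swept over a range
    of assumed joint spaces; and corrects plastic (diagenetic) distortion of
    bone meshes with rule-based affine retrodeformation. Includes a watertight
    triangle-mesh kernel (divergence-theorem mass properties, least-squares
    sphere fitting, BVH-accelerated distance and intersection queries,
    STL/OBJ/PLY input and output) and procedural synthetic specimens with
    closed-form ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
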