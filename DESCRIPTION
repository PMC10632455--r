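Package: lesionfield
Title: Electric Field Modelling of Transcranial Direct Current Stimulation in Lesioned Head Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the electric field induced by transcranial direct
    current stimulation (tDCS) in voxelised volume-conductor head models that
    include a seventh "lesion" tissue compartment. Provides multi-shell
    spherical head phantoms standing in for segmented structural MRIs, a
    finite-volume solver for the quasi-static Laplace equation with electrode
    current injection, a full-factorial generator of spherical lesion states
    (direction, distance, size, conductivity), region-of-interest field
    statistics including the lesion-direction versus current-direction angle,
    exhaustive bipolar montage optimisation under magnitude and radial-inward
    objectives, and stimulator-output individualisation. Ships synthetic
    fixtures with closed-form ground truth (layered slab conductors, analytic
    field volumes, planted-effect regression tables) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    RNifti,
    yaml,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
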