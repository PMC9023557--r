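Package: pdtkit
Title: Simulation, Dosimetry and Pose-Driven Antenna Selection for
    Wireless Photodynamic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for planning and operating implantable-LED photodynamic
    therapy (PDT) in freely moving mice.  Includes a voxel Monte Carlo
    photon transport engine and an explicit finite-difference bioheat
    solver for layered skin/tumor phantoms, five-criterion scoring and
    ranking of candidate light regimens (penetration, tumor absorbance,
    uniformity, time to target energy, temperature variation), the
    protocol dosimetry arithmetic (optical dose, duty cycle, cumulative
    drug dose), and a real-time keypoint post-processing pipeline for
    multi-animal cages: confidence filtering, snout-tail association by
    maximum weighted bipartite matching, pose vectors, per-mouse coil
    antenna selection and majority vote, with run-length and reactivation
    statistics.  A synthetic scene/track generator provides ground-truthed
    fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
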