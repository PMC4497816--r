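Package: retinosim
Title: Simulation and Quantitative Evaluation of Retinotopic Map Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of the retinotopic map between the mouse
    retina and superior colliculus (SC) under four computational models
    (Gierer potential descent, Koulakov stochastic energy minimization,
    Whitelaw Hebbian wave refinement, Willshaw marker induction) driven by
    summed Eph/ephrin gradients, for wild-type and mutant genotypes
    (Isl2-EphA3 knock-ins, ephrin-A triple knock-out, Math5 null).
    Provides the quantitative map-evaluation suite used to compare models:
    Delaunay-lattice analysis of map order, virtual retrograde injections
    with a nearest-neighbour segregation measure, cross-validated
    kernel-density contour analysis, binned 2-means collapse-point
    detection, and SC coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
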