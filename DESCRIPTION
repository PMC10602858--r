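Package: lesionPMF
Title: Free-Energy Pathway Mapping for Rad4-DNA Lesion Recognition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the free-energy pathway of DNA-lesion
    recognition by the Rad4/XPC damage sensor: center-of-mass distance
    collective variables evaluated on PDB structures, umbrella-sampling
    orchestration over a built-in overdamped Langevin engine on analytic
    toy landscapes, self-consistent WHAM estimation of potentials of mean
    force with block-bootstrap uncertainties, extraction of PMF features
    (minima, barriers, harmonic-limit crossover, plateaus, energy gaps),
    GROMOS-style RMSD clustering of conformational ensembles for
    metastable-state identification, and pairwise model comparison logic
    that orders recognition events into a pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
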