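Package: ionFootprint
Title: Relative Orientation Retrieval from Coulomb-Explosion Ion Footprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates X-ray-laser-induced Coulomb explosions of small
    proteins at desk scale and infers partial relative orientation from the
    resulting ion footprints. Provides stochastic ionization and a classical
    softened-Coulomb N-body integrator, a two-panel virtual ion detector with
    pixel binning, efficiency thinning and per-panel Gaussian blur, pairwise
    footprint-distance / relative-orientation maps with envelope-based
    distance cutoffs, explosion-reproducibility variance statistics, and the
    SO(3) uniform-rotation angle statistics that govern when orientation
    information saturates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
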