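Package: bartube
Title: Coarse-Grained Simulation of Membrane Tubulation by Curved Protein Rods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meshless, solvent-free coarse-grained model of a fluid membrane
    decorated with banana-shaped (BAR-domain-like) protein rods that carry two
    anisotropic spontaneous curvatures, one along the rod axis and one
    perpendicular to it. Provides Langevin dynamics with orientation degrees of
    freedom, constant-tension box moves, initial-condition builders for flat
    patches and vesicles, cluster/percolation/tubule observables, estimators for
    bending rigidity and in-plane diffusion, and an analytic geometric
    free-energy comparison of striped versus hexagonal (branched network) rod
    arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    generics,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
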