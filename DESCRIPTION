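Package: lignocontact
Title: Contact, Surface and Network Analysis of Lignocellulosic Biomass Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular models of pretreated lignocellulosic
    biomass: sigmoid-weighted ("soft") inter-molecular contact numbers,
    hard-cutoff enzyme binding-state classification, Gaussian-density
    isosurface areas with a Shrake-Rupley reference, interfacial areas and
    per-face coverage of cellulose fibrils, molecule-level contact networks
    with lignin aggregate morphology labels (sheet, pile, linkage), ring
    stacking crossing angles, procession lengths along fibrils, and
    translational/rotational diffusion estimation from mean squared
    displacements. Includes a synthetic biomass generator (constrained-random
    branched lignin topologies, multi-chain cellulose fibrils, multi-domain
    pseudo-cellulases, Brownian rigid-body trajectories) so every analysis can
    be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    igraph,
    bio3d,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
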