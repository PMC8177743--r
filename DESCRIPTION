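Package: rtomo
Title: Bayesian Random Tomography with Particle-Cloud Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ab initio three-dimensional reconstruction from two-dimensional
    projections taken along unknown random directions ("random tomography"),
    aimed at cryo-EM class averages and transparent-specimen microscopy. The
    unknown volume is represented as a cloud of K identical spherical Gaussian
    particles, whose X-ray projection is again a Gaussian mixture in closed
    form. Posterior simulation combines Hamiltonian Monte Carlo over particle
    positions, adaptive Metropolis-Hastings over unit quaternions, global
    rotation scans on a 600-cell tessellation of the quaternion hemisphere,
    and conjugate Gibbs updates of per-view nuisance parameters, under an
    excluded-volume Boltzmann prior with a radius-of-gyration term. Includes
    image-to-point-cloud preprocessing, DP-means coarse graining of atomic
    structures, synthetic-data generation, and evaluation tools (nearest-
    neighbour RMSD, Fourier shell correlation, gauge alignment, ICP-based
    uncertainty).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    bio3d,
    clue,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
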