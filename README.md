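# rtomo — Bayesian random tomography with particle-cloud models

`rtomo` reconstructs a three-dimensional structure from two-dimensional
projections taken along **unknown random directions** — the ab initio
reconstruction problem of single-particle cryo-EM (class averages) and of
transparent-specimen microscopy. It is aimed at structural biologists and
methods developers who want a fully Bayesian treatment: every unknown is
sampled, so estimates come with uncertainty.

## The model in brief

The volume is a cloud of K identical spherical Gaussian particles with free
centers x_k, common width σ and equal weights 1/K:

    f(r) = (1/K) Σ_k φ3(r; x_k, σ²)

Isotropic Gaussians are closed under the X-ray transform, so the projection
of the cloud along view rotation R_n is again a Gaussian mixture whose
centers are just `s·P R_n x_k + t` (P drops the z coordinate; t, s are the
per-view shift and magnification). Data enter either as images (pixelwise
Gaussian noise with per-view offset, scale and precision) or as 2D point
clouds treated as draws from the projected mixture with per-view width σ_n.
Particle positions carry a Boltzmann excluded-volume prior
exp{−βE(x)} with quartic pair repulsion below the particle diameter 2R
(β = 175; R = 0.92·(L/K)^0.42 Å for an L-atom structure) plus a weak
radius-of-gyration term exp{−α·Rg(x)}, α = 10.

Posterior simulation is Gibbs sampling: conjugate/Metropolis updates of the
nuisance parameters, adaptive quaternion random-walk Metropolis for each
view rotation (step size ×1.02 on accept / ×0.98 on reject — the fixed
point gives ≈50% acceptance), occasional global rotation scans over a
600-cell tessellation of the quaternion hemisphere (330 cells at the
coarsest level, ×8 per subdivision), and Hamiltonian Monte Carlo with 10
leapfrog steps for all particle positions jointly.

## Worked example

Simulate projections of a known 20-particle structure, reconstruct it from
scratch, and measure the recovery:

```r
library(rtomo)

cloud <- make_cloud("asymmetric-blob", K = 20, scale = 25, seed = 11)
sim   <- simulate_views(cloud, N = 30, mode = "points", M = 100,
                        sigma_n = 2, seed = 12)

config <- gibbs_config(n_sweeps = 300, K = 20,
                       prior = prior_params(beta = 175, radius = 5,
                                            alpha_rg = 10),
                       scan_frequency = 0.1, grid_level = 1)
res <- run_gibbs_restarts(sim$views, config, n_chains = 3, seed = 201)

ga   <- gauge_align(res$state$cloud$positions, cloud$positions)
errs <- pose_rotation_errors(res$state$poses, sim$poses, ga$A) * 180 / pi
round(res$chain_logposts)
#> [1] -21569 -20701 -21591
round(c(rmsd = ga$rmsd, mirrored = ga$mirrored, rot_ok = mean(errs < 10)), 3)
#>     rmsd mirrored   rot_ok
#>     0.64     0.00     1.00
```

The three numbers printed at the end say: the reconstructed cloud matches
the ground truth to 0.64 Å (nearest-neighbour RMSD after gauge alignment —
well under the 2 Å scatter of the data), this chain converged to the
reference hand (projections cannot distinguish handedness, so the aligner
checks the mirror too and reports which won), and 100% of the 30 estimated
view orientations are within 10° of the truth once the global gauge is
removed. The chain scores are the final log-posteriors of the three
independent restarts; the second chain found the dominant mode and was
selected — the other two illustrate why restarts are needed.

A shell interface wrapping the same functions is installed at
`inst/cli/rtomo` (subcommands `simulate`, `img2cloud`, `coarsegrain`,
`reconstruct`, `evaluate`, `grid`).

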