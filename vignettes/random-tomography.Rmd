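---
title: "Bayesian random tomography with particle-cloud models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian random tomography with particle-cloud models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtomo)
```

## The problem

Random tomography asks for a three-dimensional object given only
two-dimensional projections taken along *unknown, random* directions. The
canonical instance is ab initio reconstruction in single-particle cryo-EM:
each class average is an (approximately) orthographic projection of the same
particle in an unknown orientation, and no starting volume is available.
The same structure arises in microscopy of transparent mesoscopic organisms,
where magnification and in-plane shifts also vary from image to image.

`rtomo` treats this as Bayesian inference. Everything unknown — the
structure, one orientation per view, and all per-view nuisance parameters —
is a parameter of a joint posterior that is explored by Markov chain Monte
Carlo, so point estimates come with calibrated uncertainty.

## The model

**Volume representation.** The volume is a mixture of $K$ identical
spherical Gaussians with free centers $x_k \in \mathbb{R}^3$, a common
bandwidth $\sigma$, and fixed equal weights $1/K$:
$$f(r) = \frac{1}{K}\sum_{k=1}^K \phi_3(r;\, x_k, \sigma^2).$$
Each component reads as a *particle*, so $f$ is a coarse-grained,
grid-free particle cloud; resolution is controlled by $K$.

**Projection.** The X-ray (John) transform of an isotropic Gaussian along
any direction is again an isotropic Gaussian of the same width, one
dimension lower. Projection of the whole cloud therefore reduces to a rigid
map of the centers,
$$x_k' = s\, P R\, x_k + t,$$
with $R$ the view rotation, $P$ the fixed $2\times3$ matrix dropping the
third coordinate, $t$ an in-plane shift and $s$ a magnification. No
numerical integration is ever needed to form a model projection; this
closure is what makes the particle representation fast, and it is verified
against line-integral quadrature in the test suite.

**Likelihoods.** Two data models are supported.

* *Images*: pixelwise iid Gaussian noise with per-view offset $\alpha_n$,
  scale $\gamma_n$ and precision $\tau_n$ around the rendered mixture. This
  is an idealized model: there is no CTF and no correlated noise, so the
  intended inputs are high-SNR class averages rather than raw micrographs.
* *2D point clouds*: the $M_n$ points of view $n$ are treated as draws from
  the projected mixture with a per-view kernel width $\sigma_n$. Point
  clouds are either measured directly or derived from images by the
  preprocessing pipeline below.

**Priors.** Rotations are uniform over SO(3) (particles orient randomly in
ice). Precisions carry Jeffreys priors; offsets and scales are flat; shifts
get a zero-centered Gaussian. Particle positions carry a physically
motivated prior with three ingredients:

* a Boltzmann excluded-volume term $\exp\{-\beta E(x)\}$ with quartic pair
  repulsion $E = \sum_{k<k'} (1 - d_{kk'}/2R)^4$ active below the particle
  diameter $2R$; the default inverse temperature $\beta = 175$ comes from
  configurational-temperature analysis of coarse-grained biomolecules, and
  the radius follows the empirical power law $R = 0.92\,(L/K)^{0.42}$ Å for
  a structure of $L$ atoms (`predict_radius()`);
* a weak compactness term $\exp\{-\alpha_{R_g} R_g(x)\}$ on the radius of
  gyration, default $\alpha_{R_g} = 10$ (inverse Å), which discourages
  stray disconnected particles — we take the linear-in-$R_g$ form;
* a soft box: a quartic wall $((|x_i| - L_{\rm box})/w)^4$ per coordinate,
  in the same smoothness family as the repulsion so that all prior
  gradients stay continuous for Hamiltonian dynamics. By default the box
  half-width is set to 1.5 times the data extent.

## Posterior simulation

A Gibbs sweep updates three blocks in order: nuisance parameters, rotations,
positions. The order puts freshly calibrated nuisances before the rotation
moves that depend on them.

**Positions — HMC.** All $3K$ coordinates move jointly by Hamiltonian Monte
Carlo with 10 leapfrog steps per proposal and identity mass. The C++
kernels compute the mixture responsibilities that dominate the gradient
cost. The step size adapts multiplicatively (accept $\times 1.02$, reject
$\times 0.98$).

**Rotations — adaptive Metropolis.** Each view's unit quaternion is
perturbed as $q' = (q + \delta u)/\lVert q + \delta u\rVert$ with $u$
uniform in $[-1,1]^4$, 10 steps per view per sweep, with the same
$\times1.02/\times0.98$ step-size rule. The rule's fixed point
($p^\* = \ln(1/0.98)/\ln(1.02/0.98) \approx 0.505$) pins the long-run
acceptance rate near 50%, which the suite verifies by simulation.

**Rotations — global scans.** Local Metropolis cannot escape the deep
subordinate modes typical of rigid registration. With per-sweep probability
`scan_frequency` (default 0.1), the rotation conditional is evaluated at
every cell center of a 600-cell tessellation of the quaternion hemisphere
and a rotation is drawn from the resulting discrete distribution. The
600-cell's 120 vertices are the binary icosahedral quaternions; its 600
tetrahedral cells are the 4-cliques of the minimal-distance graph; keeping
the cells whose centroid has nonnegative scalar part leaves 330 covering
the upper hemisphere (q and −q encode the same rotation), and each
octasection refinement multiplies the count by 8 (2,640 at level 1).

Two refinements matter in practice:

* *During burn-in* the scan draw simply replaces the pose (raw
  exploration), and step sizes adapt.
* *After burn-in* (default: the final fifth of the sweeps) step sizes
  freeze and the scan draw is treated as an independence proposal with the
  Metropolis correction $\min\{1, \exp[\ell(\mathrm{cell}(q)) -
  \ell(q)]\}$, which is exact for cell-center proposals. Without this
  correction a scan clamps a finely refined pose back onto the coarse grid,
  systematically degrading the posterior; with it, the retained samples
  target the posterior exactly.

**Nuisances.** For images, $(\alpha_n, \gamma_n)$ have a conjugate bivariate
normal conditional (linear regression of the image on the rendered basis)
and $\tau_n$ a Gamma conditional. For point clouds the width $\sigma_n$
moves by Metropolis on $\log\sigma_n$ (the Jeffreys prior on the precision
is flat in $\log\sigma$); we deliberately avoid latent-assignment conjugate
updates to keep the sampler assignment-free. Shifts and magnifications,
when enabled, move by adaptive random-walk Metropolis — they enter the
likelihood nonlinearly, so no conjugate update exists.

**Initialization and multimodality.** Chains start from a spherical random
structure (uniform in a ball) and uniform rotations. Point-cloud widths
start overdispersed, at one third of the data extent: early rotation
conditionals are then nearly flat, poses stay mobile while the structure
forms, and the widths shrink as the fit improves — an annealing effect that
emerges from the model itself. The joint posterior is nonetheless
multimodal (structure and poses can lock each other into a consistent but
wrong configuration whose projections fit almost as well), so
`run_gibbs_restarts()` runs a few independent chains and keeps the one with
the highest final log-posterior — an internal criterion that never consults
a reference structure.

## Image preprocessing

To use the point-cloud likelihood on image data, each image is converted to
a weighted 2D point cloud: threshold at the median intensity (mask
$g > \theta$, shift masked intensities by $-\theta$), group masked pixels
into connected components under the one-pixel distance rule, keep the
component whose centroid is closest to the image center (class averages are
roughly centered), and fit an equal-weight isotropic Gaussian mixture with
a shared width by weighted EM. For transmission microscopy, intensity
decreases with optical density, so weights use $-\log g$ with $g$ clamped
to $(\varepsilon, 1-\varepsilon)$, $\varepsilon = 10^{-6}$. EM centers are
initialized by weighted sampling of distinct masked pixels; iteration stops
when the relative log-likelihood change falls below $10^{-7}$ (at most 500
iterations). The weighted log-likelihood is non-decreasing by construction,
which the suite asserts on random images.

## Reference models and evaluation

`dpmeans()` coarse-grains atomic coordinates into $K$ centers (hard
assignments, a new cluster whenever a point's squared distance to every
center exceeds $\lambda$; a bisection mode targets a requested $K$), giving
reference clouds for accuracy studies. Because the likelihood is invariant
to a global rotation of the structure (with compensating poses) and to
mirror reflection, all comparisons go through `gauge_align()`: a deterministic set of
starting rotations (octahedral plus icosahedral), each refined by ICP, for
both the model and its mirror image; `pose_rotation_errors()` then removes the same gauge from
the per-view rotations (using $S_z = \mathrm{diag}(1,1,-1)$ to compare
rotations across a handedness flip, where only the projected rows are data-
constrained). Additional metrics: directed nearest-neighbour RMSD, masked
Pearson correlation for images, Fourier shell correlation with the 0.143
resolution criterion (one-voxel shells, linear interpolation at the
crossing), and per-particle uncertainty from posterior samples via ICP
superposition plus optimal assignment (`clue::solve_LSAP`).

## Synthetic data and what the tests show

`make_cloud()` provides seeded ground-truth clouds (an asymmetric packed
blob, a GroEL-like double ring, a helix, a tetrahedron) and
`simulate_views()` draws Haar-uniform orientations and generates either
point clouds sampled from the projected mixture or rendered noisy images.
Defaults emulate the high-SNR class-average regime the method targets:
100 points per view with scatter width 2 Å against cloud extents of tens of
Å — the scatter-to-extent ratio matches a 5 Å blur on a GroEL-sized
(~140 Å) complex.

The recovery experiments in the test suite use a 20-particle asymmetric
cloud, 30 views, 300 Gibbs sweeps and 3 restarts; the global-versus-local
comparison uses a fixed 50-particle cloud and 35 views with 30
compute-matched local restarts per view. These sizes keep the whole suite
in the tens of minutes on one CPU while still exercising every moving part
at full strength. What passing them shows is that the *sampler* solves the
joint inference problem its own generative model poses; it does not show
robustness to CTF, correlated noise, heterogeneity or miscentered
particles, none of which the model represents.

## Numerical choices

* Mixture terms accumulate in log space; per-point log densities are
  floored at $-745$ (the `exp` underflow limit) instead of $-\infty$.
* Quaternions are Hamilton convention, scalar part first; `q` and `-q` map
  to identical matrices, exactly.
* The octasection splits the inner octahedron along its shortest diagonal,
  keeping child cells near-congruent; all midpoints are renormalized to the
  sphere.
* ICP uses closed-form orthogonal superposition per iteration, 100
  iterations or $10^{-8}$ relative convergence.
* CSV writers render doubles with `%.17g`, so serialization round-trips are
  bit-exact.
* HMC step sizes are frozen (and scans Metropolized) after 80% of the
  sweeps; samples meant for downstream use should be taken from that final
  phase.

## Limitations

No CTF, no correlated noise, no conformational heterogeneity, no
per-particle kernel widths, and no adaptive refinement of the rotation grid
around posterior modes. The number of particles $K$ is fixed by the user,
not inferred. Real-data workflows (EMPIAR-scale inputs) run through the
same functions but need hours of sampling, far beyond the synthetic
experiments shipped in the tests.
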