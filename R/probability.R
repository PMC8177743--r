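## Log-likelihoods, log-priors and their gradients with respect to particle
## positions. Two data models: a pixelwise Gaussian image likelihood and a
## mixture likelihood treating 2D points as draws from the projected cloud.

LOG_FLOOR <- -745  # below exp(-745) densities underflow; clamp in log space

#' Per-view nuisance parameters
#'
#' Image model: offset \code{alpha}, scale \code{gamma}, noise precision
#' \code{tau}. Point-cloud model: kernel width \code{sigma}. Shift and
#' magnification live in the \code{\link{view_pose}}.
#'
#' @param alpha,gamma,tau Image-model offset, scale and precision.
#' @param sigma Point-cloud-model kernel width.
#' @return An object of class \code{view_nuisance}.
#' @export
view_nuisance <- function(alpha = 0, gamma = 1, tau = 1, sigma = 1) {
  if (tau <= 0 || sigma <= 0) stop("precision and width must be positive")
  structure(list(alpha = alpha, gamma = gamma, tau = tau, sigma = sigma),
            class = "view_nuisance")
}

#' Hyperparameters of the position prior
#'
#' The prior over particle positions combines a Boltzmann excluded-volume
#' term \code{exp(-beta * E(x))} with quartic pair repulsion below the
#' particle diameter \code{2 * radius}, a weak compactness term
#' \code{exp(-alpha_rg * Rg(x))} on the radius of gyration, and a soft
#' quartic-wall box.
#'
#' @param beta Inverse temperature of the repulsion term (default 175, an
#'   estimate from configurational-temperature analysis of coarse-grained
#'   biomolecular structures).
#' @param radius Effective particle radius R (Angstrom); pairs repel below
#'   separation \code{2 * radius}.
#' @param alpha_rg Weight of the radius-of-gyration term (inverse Angstrom,
#'   default 10).
#' @param box_halfwidth Half-width of the soft box per coordinate (Angstrom);
#'   \code{Inf} disables the box.
#' @param wall_width Softness scale of the quartic box wall (Angstrom).
#' @return An object of class \code{prior_params}.
#' @export
prior_params <- function(beta = 175, radius = 1, alpha_rg = 10,
                         box_halfwidth = Inf, wall_width = 1) {
  if (beta < 0 || radius <= 0 || alpha_rg < 0 || wall_width <= 0)
    stop("invalid prior parameters")
  structure(list(beta = beta, radius = radius, alpha_rg = alpha_rg,
                 box_halfwidth = box_halfwidth, wall_width = wall_width),
            class = "prior_params")
}

#' Gaussian image log-likelihood
#'
#' \code{(M/2) log(tau / 2 pi) - (tau/2) * sum_m (g_m - alpha - gamma *
#' sum_k phi2(u_m; c_k, sigma^2))^2} with \code{c_k} the projected particle
#' centers; pixelwise iid Gaussian noise of precision \code{tau}.
#'
#' @param view An \code{image_view}.
#' @param cloud A \code{particle_cloud} (its \code{sigma} is the rendering
#'   width), or \code{NULL} for the empty model.
#' @param pose A \code{view_pose}.
#' @param nuisance A \code{view_nuisance} (uses \code{alpha}, \code{gamma},
#'   \code{tau}).
#' @return Scalar log-likelihood.
#' @export
image_log_likelihood <- function(view, cloud, pose, nuisance) {
  stopifnot(inherits(view, "image_view"))
  model <- render_projection_image(cloud, pose, view$grid,
                                   alpha = nuisance$alpha,
                                   gamma = nuisance$gamma)
  resid <- view$intensities - model$intensities
  M <- length(resid)
  M / 2 * log(nuisance$tau / (2 * pi)) - nuisance$tau / 2 * sum(resid^2)
}

## internal: gradient of the image log-likelihood wrt particle positions,
## using the x/y separability of the 2D kernel
image_position_grad <- function(view, cloud, pose, nuisance) {
  R <- quaternion_to_matrix(pose$q)
  pr <- project_cloud(cloud, pose)
  co <- view$grid$coords
  G <- gauss1d_profiles(co, pr$centers, pr$sigma)
  model <- nuisance$alpha + nuisance$gamma * (G$gx %*% t(G$gy))
  E <- view$intensities - model
  s2 <- pr$sigma^2
  dx <- outer(co, pr$centers[, 1], "-")   # n x K: x_i - cx_k
  dy <- outer(co, pr$centers[, 2], "-")
  gcx <- colSums((G$gx * dx) * (E %*% G$gy)) / s2
  gcy <- colSums((G$gy * dy) * (t(E) %*% G$gx)) / s2
  Gc <- nuisance$tau * nuisance$gamma * cbind(gcx, gcy)  # K x 2, d ll / d c_k
  pose$mag * Gc %*% R[1:2, , drop = FALSE]
}

#' Point-cloud log-likelihood
#'
#' Treats the M observed 2D points of a view as independent draws from the
#' projected cloud: \code{sum_m log[(1/K) sum_k phi2(y_m; mag * P R x_k +
#' shift, sigma_n^2)]}, accumulated with log-sum-exp.
#'
#' @param view A \code{point_cloud_view}.
#' @param cloud A \code{particle_cloud}.
#' @param pose A \code{view_pose} (shift and magnification enter the
#'   projected centers).
#' @param nuisance A \code{view_nuisance}; its \code{sigma} is the per-view
#'   kernel width of this likelihood (not the 3D rendering width).
#' @return Scalar log-likelihood.
#' @export
cloud_log_likelihood <- function(view, cloud, pose, nuisance) {
  stopifnot(inherits(view, "point_cloud_view"))
  ctr <- project_cloud(cloud, pose)$centers
  cpp_cloud_loglik(view$points, ctr, nuisance$sigma^2, LOG_FLOOR)
}

## internal: M x K matrix of log phi2(y_m; c_k, sigma^2)
log_phi_matrix <- function(points, cloud, pose, sigma) {
  ctr <- project_cloud(cloud, pose)$centers
  d2 <- outer(points[, 1], ctr[, 1], "-")^2 +
        outer(points[, 2], ctr[, 2], "-")^2
  -log(2 * pi * sigma^2) - d2 / (2 * sigma^2)
}

## internal: row-wise log-sum-exp (columnwise pmax: vectorized row maxima)
log_sum_exp_rows <- function(lp) {
  mx <- lp[, 1]
  for (k in seq_len(ncol(lp))[-1]) mx <- pmax(mx, lp[, k])
  mx[!is.finite(mx)] <- LOG_FLOOR
  mx + log(rowSums(exp(lp - mx)))
}

## internal: gradient of the point-cloud log-likelihood wrt positions
cloud_position_grad <- function(view, cloud, pose, nuisance) {
  R <- quaternion_to_matrix(pose$q)
  ctr <- project_cloud(cloud, pose)$centers
  Gc <- cpp_cloud_grad_centers(view$points, ctr, nuisance$sigma^2)
  pose$mag * Gc %*% R[1:2, , drop = FALSE]
}

#' Log-likelihood of one view (dispatching on the data type)
#'
#' @param view An \code{image_view} or \code{point_cloud_view}.
#' @param cloud,pose,nuisance See \code{\link{image_log_likelihood}} and
#'   \code{\link{cloud_log_likelihood}}.
#' @return Scalar log-likelihood.
#' @export
view_log_likelihood <- function(view, cloud, pose, nuisance) {
  if (inherits(view, "image_view"))
    image_log_likelihood(view, cloud, pose, nuisance)
  else cloud_log_likelihood(view, cloud, pose, nuisance)
}

## internal dispatch for position gradients
view_position_grad <- function(view, cloud, pose, nuisance) {
  if (inherits(view, "image_view"))
    image_position_grad(view, cloud, pose, nuisance)
  else cloud_position_grad(view, cloud, pose, nuisance)
}

#' Quartic excluded-volume energy
#'
#' \code{sum_{k<k'} (1 - d_kk' / 2R)^4} over pairs closer than the particle
#' diameter \code{2R}; zero for well-separated configurations, 1 for a
#' coincident pair. The quartic form keeps the gradient continuous at
#' \code{d = 2R}.
#'
#' @param positions \code{K x 3} matrix.
#' @param radius Particle radius R.
#' @return List with \code{energy} (scalar) and \code{grad} (\code{K x 3}).
#' @export
repulsion_energy <- function(positions, radius) {
  if (radius <= 0) stop("radius must be positive")
  K <- nrow(positions)
  grad <- matrix(0, K, 3)
  if (K < 2) return(list(energy = 0, grad = grad))
  D <- as.matrix(stats::dist(positions))
  two_r <- 2 * radius
  act <- D < two_r & upper.tri(D)
  energy <- sum((1 - D[act] / two_r)^4)
  pair <- which(D < two_r & upper.tri(D), arr.ind = TRUE)
  for (idx in seq_len(nrow(pair))) {
    k <- pair[idx, 1]; kk <- pair[idx, 2]
    d <- max(D[k, kk], 1e-12)
    coef <- -4 * (1 - d / two_r)^3 / (two_r * d)
    dvec <- coef * (positions[k, ] - positions[kk, ])
    grad[k, ] <- grad[k, ] + dvec
    grad[kk, ] <- grad[kk, ] - dvec
  }
  list(energy = energy, grad = grad)
}

#' Radius of gyration
#'
#' RMS distance of the particles from their centroid.
#'
#' @param positions \code{K x 3} matrix.
#' @return List with \code{rg} and \code{grad} (\code{K x 3}; zero at
#'   degenerate single-point configurations).
#' @export
radius_gyration <- function(positions) {
  K <- nrow(positions)
  ctr <- colMeans(positions)
  dev <- positions - matrix(ctr, K, 3, byrow = TRUE)
  rg <- sqrt(sum(dev^2) / K)
  grad <- if (rg > 1e-12) dev / (K * rg) else matrix(0, K, 3)
  list(rg = rg, grad = grad)
}

## internal: soft quartic box wall, per-coordinate ((|x|-L)/w)^4 beyond L
box_energy <- function(positions, halfwidth, wall_width) {
  if (!is.finite(halfwidth))
    return(list(energy = 0, grad = 0 * positions))
  over <- pmax(abs(positions) - halfwidth, 0)
  energy <- sum((over / wall_width)^4)
  grad <- 4 * over^3 / wall_width^4 * sign(positions)
  list(energy = energy, grad = grad)
}

#' Log-prior over particle positions with gradient
#'
#' \code{-beta * E(x) - alpha_rg * Rg(x) - E_box(x)} up to an additive
#' constant.
#'
#' @param positions \code{K x 3} matrix.
#' @param prior A \code{\link{prior_params}}.
#' @return List with \code{value} and \code{grad} (\code{K x 3}).
#' @export
log_prior_positions <- function(positions, prior) {
  rep_ <- repulsion_energy(positions, prior$radius)
  rg <- radius_gyration(positions)
  bx <- box_energy(positions, prior$box_halfwidth, prior$wall_width)
  list(value = -prior$beta * rep_$energy - prior$alpha_rg * rg$rg - bx$energy,
       grad = -prior$beta * rep_$grad - prior$alpha_rg * rg$grad - bx$grad)
}

#' Conditional log-density of a view's rotation
#'
#' The prior over rotations is uniform on SO(3), so the conditional is the
#' view likelihood evaluated at \code{R = quaternion_to_matrix(q)} (shift and
#' magnification taken from \code{pose}). Invariant under \code{q -> -q}.
#'
#' @param q Unit quaternion.
#' @param view An \code{image_view} or \code{point_cloud_view}.
#' @param cloud A \code{particle_cloud}.
#' @param nuisance A \code{view_nuisance}.
#' @param pose A \code{view_pose} supplying shift and magnification.
#' @return Scalar log-density (unnormalized).
#' @export
rotation_conditional_logpdf <- function(q, view, cloud, nuisance,
                                        pose = view_pose()) {
  p <- view_pose(q / sqrt(sum(q^2)), shift = pose$shift, mag = pose$mag)
  view_log_likelihood(view, cloud, p, nuisance)
}
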