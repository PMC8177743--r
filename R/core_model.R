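## Particle-cloud volume model. A volume f(r) is a mixture of K identical
## spherical Gaussians with equal weights 1/K; its X-ray projection along any
## direction is again a K-component 2D Gaussian mixture with the same width,
## so projection reduces to a rigid map of the particle centers.

#' Particle-cloud representation of a 3D volume
#'
#' A cloud of \code{K} particles at free 3D positions, all carrying the same
#' isotropic Gaussian kernel of width \code{sigma} and equal weight
#' \code{1/K}. The implied volume is
#' \code{f(r) = (1/K) sum_k phi3(r; x_k, sigma^2)}.
#'
#' @param positions \code{K x 3} numeric matrix of particle centers (Angstrom).
#' @param sigma Kernel bandwidth (Angstrom), strictly positive.
#' @return An object of class \code{particle_cloud} with fields
#'   \code{positions}, \code{sigma} and \code{weight} (\code{= 1/K}).
#' @export
particle_cloud <- function(positions, sigma) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be a K x 3 matrix")
  if (nrow(positions) < 1) stop("need at least one particle")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be a finite positive scalar")
  structure(list(positions = unname(positions), sigma = sigma,
                 weight = 1 / nrow(positions)),
            class = "particle_cloud")
}

#' @export
print.particle_cloud <- function(x, ...) {
  cat("particle_cloud:", nrow(x$positions), "particles, kernel width",
      format(x$sigma), "A\n")
  invisible(x)
}

#' Per-view pose: orientation, in-plane shift, magnification
#'
#' @param q Unit quaternion (Hamilton, scalar first) giving the view
#'   orientation; projection is along the rotated z-axis.
#' @param shift Length-2 in-plane translation (same units as image
#'   coordinates), applied after projection and magnification.
#' @param mag Magnification factor (default 1) scaling projected coordinates.
#' @return An object of class \code{view_pose}.
#' @export
view_pose <- function(q = c(1, 0, 0, 0), shift = c(0, 0), mag = 1) {
  nq <- sqrt(sum(q^2))
  if (abs(nq - 1) > 1e-9) stop("pose quaternion must be unit-norm")
  if (!is.finite(mag) || mag <= 0) stop("magnification must be positive")
  structure(list(q = q / nq, shift = as.numeric(shift), mag = mag),
            class = "view_pose")
}

#' The fixed 2x3 orthographic projection matrix
#'
#' Drops the third coordinate: projection along z after the model has been
#' rotated into the view frame.
#'
#' @return The 2x3 matrix \code{rbind(c(1,0,0), c(0,1,0))}.
#' @export
projection_matrix <- function() {
  matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
}

#' Evaluate a spherical Gaussian density
#'
#' \code{(2 pi sigma^2)^(-d/2) exp(-||r - center||^2 / (2 sigma^2))} with
#' \code{d} the dimension, inferred from the columns of \code{r}.
#'
#' @param r Evaluation points, an \code{n x d} matrix (or a length-d vector).
#' @param center Kernel center, length-d.
#' @param sigma Bandwidth, strictly positive.
#' @return Vector of n strictly positive densities.
#' @export
gaussian_eval <- function(r, center, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  d <- ncol(r)
  if (!d %in% 1:3) stop("dimension must be 1, 2 or 3")
  if (length(center) != d) stop("center has wrong length")
  sq <- rowSums((r - matrix(center, nrow(r), d, byrow = TRUE))^2)
  (2 * pi * sigma^2)^(-d / 2) * exp(-sq / (2 * sigma^2))
}

#' Rigid transformation of a particle cloud
#'
#' Maps every particle \code{x_k} to \code{R x_k + t}; the kernel width and
#' the equal weights are untouched, so this is exactly the rigid motion of
#' the implied volume.
#'
#' @param cloud A \code{particle_cloud}.
#' @param rotation 3x3 proper rotation matrix (checked to 1e-8).
#' @param t Length-3 translation.
#' @return The transformed \code{particle_cloud}.
#' @export
rigid_transform <- function(cloud, rotation, t = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "particle_cloud"))
  if (!is_rotation(rotation)) stop("not a proper rotation matrix")
  pos <- cloud$positions %*% t(rotation) +
    matrix(t, nrow(cloud$positions), 3, byrow = TRUE)
  particle_cloud(pos, cloud$sigma)
}

#' Closed-form X-ray projection of a particle cloud
#'
#' The line integral of an isotropic 3D Gaussian along any direction is an
#' isotropic 2D Gaussian of the same width, so projecting the cloud reduces
#' to mapping the centers: \code{x'_k = mag * P R x_k + shift}.
#'
#' @param cloud A \code{particle_cloud}.
#' @param pose A \code{view_pose}.
#' @return List with \code{centers} (\code{K x 2}) and \code{sigma} (the
#'   projected kernel width, equal to the 3D width; note the point-cloud
#'   likelihood uses a per-view width instead).
#' @export
project_cloud <- function(cloud, pose) {
  stopifnot(inherits(cloud, "particle_cloud"), inherits(pose, "view_pose"))
  R <- quaternion_to_matrix(pose$q)
  xy <- (cloud$positions %*% t(R))[, 1:2, drop = FALSE]
  centers <- pose$mag * xy +
    matrix(pose$shift, nrow(xy), 2, byrow = TRUE)
  list(centers = centers, sigma = cloud$sigma)
}

#' Regular square pixel grid
#'
#' Pixel centers at \code{(i - (n-1)/2) * pixel_size} for 0-based index
#' \code{i}, so the grid is centered on the projection origin.
#'
#' @param n Pixels per side.
#' @param pixel_size Pixel edge length (Angstrom per pixel).
#' @return List with \code{n}, \code{pixel_size} and \code{coords}, the n
#'   pixel-center coordinates along one axis.
#' @export
image_grid <- function(n, pixel_size = 1) {
  stopifnot(n >= 1, pixel_size > 0)
  list(n = as.integer(n), pixel_size = pixel_size,
       coords = (seq_len(n) - 1 - (n - 1) / 2) * pixel_size)
}

#' Render the projection image of a cloud
#'
#' Pixel \code{m} receives \code{alpha + gamma * sum_k phi2(u_m; c_k,
#' sigma^2)} where the \code{c_k} are the projected particle centers. The 2D
#' kernel factorizes over x and y, so the image is accumulated from 1D
#' Gaussian profiles.
#'
#' @param cloud A \code{particle_cloud}, or \code{NULL} for an empty model
#'   (constant image \code{alpha}).
#' @param pose A \code{view_pose}.
#' @param grid An \code{\link{image_grid}}.
#' @param alpha Additive offset.
#' @param gamma Multiplicative scale of the mixture term.
#' @return An \code{image_view}: list with \code{intensities} (n x n matrix,
#'   first index = x, second = y), \code{pixel_size} and \code{grid}.
#' @export
render_projection_image <- function(cloud, pose, grid, alpha = 0, gamma = 1) {
  img <- matrix(alpha, grid$n, grid$n)
  if (!is.null(cloud)) {
    pr <- project_cloud(cloud, pose)
    G <- gauss1d_profiles(grid$coords, pr$centers, pr$sigma)
    img <- img + gamma * (G$gx %*% t(G$gy))
  }
  image_view(img, grid$pixel_size)
}

## internal: n x K matrices of 1D Gaussian profiles along x and y
gauss1d_profiles <- function(coords, centers, sigma) {
  nrm <- 1 / sqrt(2 * pi * sigma^2)
  gx <- nrm * exp(-outer(coords, centers[, 1], "-")^2 / (2 * sigma^2))
  gy <- nrm * exp(-outer(coords, centers[, 2], "-")^2 / (2 * sigma^2))
  list(gx = gx, gy = gy)
}

#' Image container
#'
#' @param intensities Square numeric matrix of pixel intensities; the first
#'   index runs along x, the second along y, centered per
#'   \code{\link{image_grid}}.
#' @param pixel_size Angstrom per pixel.
#' @return An object of class \code{image_view}.
#' @export
image_view <- function(intensities, pixel_size = 1) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != ncol(intensities))
    stop("image must be square")
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 grid = image_grid(nrow(intensities), pixel_size)),
            class = "image_view")
}

#' 2D point-cloud view container
#'
#' @param points \code{M x 2} matrix of 2D coordinates.
#' @param weights Optional per-point nonnegative weights.
#' @return An object of class \code{point_cloud_view}.
#' @export
point_cloud_view <- function(points, weights = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 1)
    stop("points must be a nonempty M x 2 matrix")
  if (!all(is.finite(points))) stop("points must be finite")
  structure(list(points = unname(points), weights = weights),
            class = "point_cloud_view")
}

#' Render the cloud as a voxelized 3D density
#'
#' Voxel \code{(i,j,l)} receives \code{(1/K) sum_k phi3(r_ijl; x_k,
#' sigma^2)}; total mass (voxel sum times voxel volume) is ~1 when the grid
#' covers the kernel support.
#'
#' @param cloud A \code{particle_cloud}.
#' @param n Voxels per side.
#' @param voxel_size Voxel edge length (Angstrom); a warning is issued when
#'   it exceeds the kernel width.
#' @return List with \code{density} (n x n x n array), \code{voxel_size} and
#'   \code{coords} (axis voxel centers).
#' @export
render_volume <- function(cloud, n, voxel_size = 1) {
  stopifnot(inherits(cloud, "particle_cloud"))
  if (n < 1) stop("empty voxel grid")
  if (voxel_size >= cloud$sigma)
    warning("voxel size >= kernel width; the map will undersample the kernels")
  coords <- (seq_len(n) - 1 - (n - 1) / 2) * voxel_size
  s2 <- 2 * cloud$sigma^2
  nrm <- (2 * pi * cloud$sigma^2)^(-3 / 2)
  den <- array(0, c(n, n, n))
  w <- cloud$weight
  for (k in seq_len(nrow(cloud$positions))) {
    gx <- exp(-(coords - cloud$positions[k, 1])^2 / s2)
    gy <- exp(-(coords - cloud$positions[k, 2])^2 / s2)
    gz <- exp(-(coords - cloud$positions[k, 3])^2 / s2)
    den <- den + w * nrm * outer(outer(gx, gy), gz)
  }
  list(density = den, voxel_size = voxel_size, coords = coords)
}
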