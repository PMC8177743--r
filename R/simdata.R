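## Seeded synthetic data: ground-truth particle clouds, Haar-uniform view
## orientations, projected 2D point clouds (sampled from the projected
## mixture) and rendered noisy projection images. Defaults emulate the
## high-SNR class-average regime: well-separated particles, per-view point
## clouds whose scatter is small relative to the cloud extent.

#' Generate a ground-truth particle cloud
#'
#' Presets: \code{"asymmetric-blob"} (particles packed at random in a ball
#' with a minimum-separation constraint; generically has no nontrivial point
#' symmetry), \code{"double-ring"} (two stacked twisted rings, GroEL-like),
#' \code{"helix"}, and \code{"tetrahedron"} (K = 4, regular).
#'
#' @param preset Preset name.
#' @param K Number of particles.
#' @param scale Overall size scale (Angstrom): ball radius, ring radius, or
#'   helix radius.
#' @param seed RNG seed; the cloud is deterministic given the seed.
#' @param sigma Kernel width attached to the cloud (default
#'   \code{scale / 10}).
#' @return A \code{particle_cloud}.
#' @export
make_cloud <- function(preset = c("asymmetric-blob", "double-ring", "helix",
                                  "tetrahedron"),
                       K = 20, scale = 25, seed = 1, sigma = scale / 10) {
  preset <- match.arg(preset)
  set.seed(seed)
  X <- switch(preset,
    "asymmetric-blob" = {
      min_sep <- 2 * 0.92 * scale * (0.15 / K)^(1 / 3)
      pts <- matrix(NA_real_, K, 3)
      k <- 0; tries <- 0
      while (k < K) {
        cand <- stats::rnorm(3)
        cand <- cand / sqrt(sum(cand^2)) * scale * stats::runif(1)^(1 / 3)
        tries <- tries + 1
        if (k == 0 || min(sqrt(rowSums((pts[seq_len(k), , drop = FALSE] -
            matrix(cand, k, 3, byrow = TRUE))^2))) > min_sep) {
          k <- k + 1; pts[k, ] <- cand
        }
        if (tries > 5000 * K) { min_sep <- min_sep * 0.9; tries <- 0 }
      }
      pts
    },
    "double-ring" = {
      kh <- K %/% 2
      ang1 <- 2 * pi * seq_len(kh) / kh
      ang2 <- 2 * pi * (seq_len(K - kh) + 0.3) / (K - kh)
      rbind(cbind(scale * cos(ang1), scale * sin(ang1), -scale / 3),
            cbind(scale * cos(ang2), scale * sin(ang2), scale / 3))
    },
    "helix" = {
      tt <- seq(0, 4 * pi, length.out = K)
      cbind(scale * cos(tt), scale * sin(tt), scale * (tt / (2 * pi) - 1))
    },
    "tetrahedron" = {
      if (K != 4) warning("tetrahedron preset uses K = 4")
      scale / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1),
                              c(-1, 1, -1), c(-1, -1, 1))
    })
  particle_cloud(X, sigma)
}

#' Check a cloud for approximate point-group symmetry
#'
#' Scans the 24 octahedral rotations (other than the identity) applied about
#' the centroid and reports whether any maps the cloud onto itself within
#' \code{tol}.
#'
#' @param cloud A \code{particle_cloud}.
#' @param tol Match tolerance (default: the kernel width).
#' @return \code{TRUE} if a nontrivial symmetry is found.
#' @export
has_point_symmetry <- function(cloud, tol = cloud$sigma) {
  X <- cloud$positions
  ctr <- colMeans(X)
  Xc <- X - matrix(ctr, nrow(X), 3, byrow = TRUE)
  for (R in octahedral_rotations()) {
    if (max(abs(R - diag(3))) < 1e-12) next
    if (rmsd_nn(Xc, Xc %*% t(R), symmetric = TRUE) < tol) return(TRUE)
  }
  FALSE
}

#' Simulate projection data from a cloud
#'
#' Poses are Haar-uniform over SO(3). Point mode: each of the M points of a
#' view is a draw from the projected mixture (pick a particle uniformly, add
#' 2D Gaussian noise of width \code{sigma_n}); \code{deterministic = TRUE}
#' instead returns exactly the K projected centers. Image mode: the cloud is
#' rendered with blur width \code{blur} and pixelwise white noise of
#' precision \code{tau} is added.
#'
#' @param cloud A \code{particle_cloud}.
#' @param N Number of views.
#' @param mode \code{"points"} or \code{"images"}.
#' @param M Points per view (point mode).
#' @param sigma_n True per-view kernel width of the point scatter (Angstrom).
#' @param deterministic Point mode: return projected centers, no scatter.
#' @param alpha,gamma,tau Image-model offset, scale, noise precision.
#' @param blur Rendering kernel width for image mode (Angstrom; 5 matches a
#'   typical class-average blur).
#' @param n_pix Image side (pixels).
#' @param pixel_size Angstrom per pixel; default sizes the field of view to
#'   2.5x the cloud extent.
#' @param seed RNG seed.
#' @return List with \code{views} (list of \code{point_cloud_view} /
#'   \code{image_view}), \code{poses} (ground-truth \code{view_pose}s) and
#'   \code{params}.
#' @export
simulate_views <- function(cloud, N, mode = c("points", "images"), M = 100,
                           sigma_n = 2, deterministic = FALSE,
                           alpha = 0, gamma = 1, tau = 1e4, blur = 5,
                           n_pix = 48, pixel_size = NULL, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  qs <- random_quaternion(N)
  poses <- lapply(seq_len(N), function(n) view_pose(qs[n, ]))
  K <- nrow(cloud$positions)
  ext <- max(abs(cloud$positions)) + 3 * cloud$sigma
  if (is.null(pixel_size)) pixel_size <- 2.5 * ext / n_pix
  views <- vector("list", N)
  for (n in seq_len(N)) {
    if (mode == "points") {
      ctr <- project_cloud(cloud, poses[[n]])$centers
      if (deterministic) {
        views[[n]] <- point_cloud_view(ctr)
      } else {
        comp <- sample.int(K, M, replace = TRUE)
        pts <- ctr[comp, , drop = FALSE] + sigma_n * matrix(stats::rnorm(2 * M), M, 2)
        views[[n]] <- point_cloud_view(pts)
      }
    } else {
      cl <- cloud; cl$sigma <- blur
      img <- render_projection_image(cl, poses[[n]],
                                     image_grid(n_pix, pixel_size),
                                     alpha = alpha, gamma = gamma)
      noise <- matrix(stats::rnorm(n_pix^2, sd = 1 / sqrt(tau)), n_pix, n_pix)
      views[[n]] <- image_view(img$intensities + noise, pixel_size)
    }
  }
  list(views = views, poses = poses,
       params = list(mode = mode, M = M, sigma_n = sigma_n, alpha = alpha,
                     gamma = gamma, tau = tau, blur = blur,
                     pixel_size = pixel_size, seed = seed))
}
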