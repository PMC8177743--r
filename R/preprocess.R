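## Conversion of projection images to weighted 2D point clouds: median (or
## user) thresholding, connected components on the pixel lattice, selection
## of the most central component, and an equal-weight Gaussian-mixture EM fit
## of point positions to the masked intensities.

#' Threshold an image and shift masked intensities
#'
#' Pixels with intensity strictly above \code{theta} form the mask; their
#' intensities are shifted by \code{-theta} (so they are nonnegative), all
#' other pixels are set to zero.
#'
#' @param image An \code{\link{image_view}} or a numeric matrix.
#' @param theta Numeric threshold, or \code{"median"} for the median
#'   intensity (the usual choice for cryo-EM class averages).
#' @return List with \code{mask} (logical matrix), \code{shifted} (numeric
#'   matrix of shifted intensities) and \code{theta}.
#' @export
threshold_mask <- function(image, theta = "median") {
  g <- if (inherits(image, "image_view")) image$intensities else as.matrix(image)
  if (length(g) == 0) stop("empty image")
  if (identical(theta, "median")) theta <- stats::median(g)
  mask <- g > theta
  if (!any(mask)) warning("empty mask: no pixel exceeds the threshold")
  shifted <- ifelse(mask, g - theta, 0)
  list(mask = mask, shifted = shifted, theta = theta)
}

#' Connected components of a pixel mask
#'
#' Masked pixels are vertices; edges join pixels at Euclidean distance at
#' most one (4-connectivity on the square lattice). Components are the
#' maximal connected sets.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
connected_components <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

#' Select the component closest to the image center
#'
#' Returns the label of the component whose pixel centroid minimizes the
#' distance to the image center; ties go to the larger component, then the
#' lowest label. Class averages are assumed roughly centered, so the central
#' component carries the particle signal.
#'
#' @param labels Label matrix from \code{\link{connected_components}}.
#' @return List with \code{label} and \code{mask} of the selected component.
#' @export
central_component <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) stop("no components")
  center <- c((nrow(labels) + 1) / 2, (ncol(labels) + 1) / 2)
  stats <- t(vapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    c(dist = sqrt(sum((colMeans(px) - center)^2)), size = nrow(px))
  }, numeric(2)))
  ord <- order(stats[, 1], -stats[, 2], ids)
  best <- ids[ord[1]]
  list(label = best, mask = labels == best)
}

#' Fit an equal-weight Gaussian point cloud to a masked image
#'
#' Expectation Maximization on an M-component isotropic 2D mixture with
#' fixed equal weights \code{1/M} and a shared width, fitted to the masked
#' pixel positions with per-pixel weights (the shifted intensities, or
#' \code{-log g} for transmission microscopy where intensity decreases with
#' optical density). EM centers are initialized by weighted sampling of M
#' distinct masked pixels; the shared width starts at half the bounding-box
#' diagonal divided by \code{sqrt(M)}.
#'
#' @param shifted Numeric matrix of masked (nonnegative) intensities; pixels
#'   with zero weight are ignored.
#' @param M Number of mixture components (points).
#' @param mode \code{"linear"} (weights = intensities) or \code{"neglog"}
#'   (weights = \code{-log} of intensities clamped to (0, 1)).
#' @param seed Optional RNG seed for the initialization.
#' @param max_iter,tol Convergence controls: stop when the relative change of
#'   the weighted log-likelihood drops below \code{tol}.
#' @return A \code{point_cloud_view} whose \code{points} are the fitted
#'   centers (pixel coordinates), with attributes \code{sigma} (shared
#'   width, pixels), \code{loglik} (per-iteration trace, non-decreasing) and
#'   \code{gamma} (total weight mass).
#' @export
fit_point_cloud <- function(shifted, M, mode = c("linear", "neglog"),
                            seed = NULL, max_iter = 500, tol = 1e-7) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  px <- which(shifted > 0, arr.ind = TRUE)
  w <- shifted[px]
  if (mode == "neglog") {
    eps <- 1e-6
    w <- -log(pmin(pmax(shifted[px], eps), 1 - eps))
    w <- pmax(w, 0)
  }
  keep <- w > 0
  px <- px[keep, , drop = FALSE]; w <- w[keep]
  if (nrow(px) < M) stop("fewer positive-weight pixels than components")
  U <- cbind(px[, 1], px[, 2]) * 1.0
  W <- sum(w)
  ## init: M distinct pixels by weighted sampling; sigma from bounding box
  ctr <- U[sample.int(nrow(U), M, prob = w), , drop = FALSE]
  bb <- sqrt(sum((apply(U, 2, max) - apply(U, 2, min))^2))
  sigma <- max(bb / (2 * sqrt(M)), 0.5)
  ll_trace <- numeric(0)
  sqdist <- function(ctr) {
    outer(U[, 1], ctr[, 1], "-")^2 + outer(U[, 2], ctr[, 2], "-")^2
  }
  for (it in seq_len(max_iter)) {
    lp <- -log(2 * pi * sigma^2) - sqdist(ctr) / (2 * sigma^2)
    lse <- log_sum_exp_rows(lp)
    ll <- sum(w * (lse - log(M)))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <=
          tol * abs(ll_trace[it - 1])) break
    resp <- exp(lp - lse) * w            # weighted responsibilities
    Nk <- pmax(colSums(resp), 1e-12)
    ctr <- (t(resp) %*% U) / Nk
    sigma <- sqrt(max(sum(resp * sqdist(ctr)) / (2 * W), 1e-6))
  }
  out <- point_cloud_view(ctr, weights = NULL)
  attr(out, "sigma") <- sigma
  attr(out, "loglik") <- ll_trace
  attr(out, "gamma") <- W
  out
}

#' Full image-to-point-cloud pipeline
#'
#' Threshold, connected components, central-component selection, EM fit.
#' Point coordinates are returned in the physical (Angstrom) frame of the
#' image grid.
#'
#' @param image An \code{\link{image_view}}.
#' @param M Number of points.
#' @param theta Threshold (\code{"median"} or numeric).
#' @param mode Weighting mode, see \code{\link{fit_point_cloud}}.
#' @param seed Optional RNG seed.
#' @return A \code{point_cloud_view} in physical coordinates with attributes
#'   \code{sigma} (Angstrom), \code{theta} and \code{component_size}.
#' @export
image_to_cloud <- function(image, M, theta = "median",
                           mode = c("linear", "neglog"), seed = NULL) {
  stopifnot(inherits(image, "image_view"))
  mode <- match.arg(mode)
  th <- threshold_mask(image, theta)
  labels <- connected_components(th$mask)
  cc <- central_component(labels)
  shifted <- ifelse(cc$mask, th$shifted, 0)
  fit <- fit_point_cloud(shifted, M, mode = mode, seed = seed)
  ## pixel index (1-based) -> centered physical coordinate
  n <- image$grid$n
  phys <- (fit$points - 1 - (n - 1) / 2) * image$pixel_size
  out <- point_cloud_view(phys)
  attr(out, "sigma") <- attr(fit, "sigma") * image$pixel_size
  attr(out, "loglik") <- attr(fit, "loglik")
  attr(out, "theta") <- th$theta
  attr(out, "component_size") <- sum(cc$mask)
  out
}
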