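## Model assessment. The posterior is invariant to a global rotation of the
## particle cloud (with compensating per-view rotations) and to mirror
## reflection, so reconstructions must be gauge-aligned before any comparison
## with a reference.

#' Nearest-neighbour RMSD
#'
#' Root mean square, over reference points, of the distance to the closest
#' model point. Asymmetric by construction (reference -> model); set
#' \code{symmetric = TRUE} to average both directions.
#'
#' @param reference,model Point matrices (\code{n x d}).
#' @param symmetric Average the two directed values.
#' @return RMSD in the coordinate units.
#' @export
rmsd_nn <- function(reference, model, symmetric = FALSE) {
  reference <- as.matrix(reference); model <- as.matrix(model)
  d <- directed_rmsd(reference, model)
  if (symmetric) d <- sqrt((d^2 + directed_rmsd(model, reference)^2) / 2)
  d
}

## internal: rms over rows of `from` of distance to nearest row of `to`
directed_rmsd <- function(from, to) {
  d2min <- min_sq_dists(from, to)
  sqrt(mean(d2min))
}

## internal: per-row minimal squared distances, blocked to bound memory
min_sq_dists <- function(from, to) {
  n <- nrow(from)
  out <- numeric(n)
  block <- max(1, floor(2e6 / nrow(to)))
  for (s in seq(1, n, by = block)) {
    idx <- s:min(n, s + block - 1)
    cross <- from[idx, , drop = FALSE] %*% t(to)
    d2 <- outer(rowSums(from[idx, , drop = FALSE]^2), rowSums(to^2), "+") -
      2 * cross
    out[idx] <- pmax(apply(d2, 1, min), 0)
  }
  out
}

#' Pearson cross-correlation of two images
#'
#' @param a,b Equal-shape numeric matrices or \code{image_view}s.
#' @param mask Optional logical matrix restricting the correlated pixels.
#' @return Correlation coefficient in \code{[-1, 1]}.
#' @export
cross_correlation <- function(a, b, mask = NULL) {
  va <- if (inherits(a, "image_view")) a$intensities else as.matrix(a)
  vb <- if (inherits(b, "image_view")) b$intensities else as.matrix(b)
  if (!all(dim(va) == dim(vb))) stop("shape mismatch")
  if (!is.null(mask)) { va <- va[mask]; vb <- vb[mask] }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(as.vector(va), as.vector(vb))
}

#' Fourier shell correlation and resolution at the 0.143 criterion
#'
#' Per-shell normalized correlation of the discrete Fourier coefficients of
#' two cubic maps; shells one Fourier voxel wide. The resolution is the
#' reciprocal of the spatial frequency at the first downward crossing of the
#' threshold, linearly interpolated between shells, and is reported only if
#' the curve starts above the threshold.
#'
#' @param map_a,map_b Equal-shape cubic 3D arrays.
#' @param voxel_size Voxel edge (Angstrom).
#' @param threshold FSC threshold (default 0.143).
#' @return List with \code{freq} (1/Angstrom), \code{fsc}, \code{resolution}
#'   (Angstrom or \code{NA}) and \code{zero_power} (shells lacking signal,
#'   reported as 0).
#' @export
fsc <- function(map_a, map_b, voxel_size = 1, threshold = 0.143) {
  if (!all(dim(map_a) == dim(map_b))) stop("shape mismatch")
  n <- dim(map_a)[1]
  if (!all(dim(map_a) == n)) stop("maps must be cubic")
  Fa <- stats::fft(map_a); Fb <- stats::fft(map_b)
  idx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # per-axis frequency index
  ii <- array(idx, c(n, n, n))
  jj <- aperm(ii, c(2, 1, 3)); kk <- aperm(ii, c(3, 2, 1))
  shell <- round(sqrt(ii^2 + jj^2 + kk^2))
  smax <- n %/% 2
  fsc_v <- numeric(smax); zero_power <- logical(smax)
  for (s in seq_len(smax)) {
    sel <- shell == s
    num <- Re(sum(Fa[sel] * Conj(Fb[sel])))
    den <- sqrt(sum(Mod(Fa[sel])^2) * sum(Mod(Fb[sel])^2))
    if (den == 0) { fsc_v[s] <- 0; zero_power[s] <- TRUE }
    else fsc_v[s] <- num / den
  }
  freq <- seq_len(smax) / (n * voxel_size)
  resolution <- NA_real_
  if (fsc_v[1] > threshold) {
    below <- which(fsc_v < threshold)
    if (length(below)) {
      s <- below[1]
      f_cross <- if (s == 1) freq[1] else {
        frac <- (fsc_v[s - 1] - threshold) / (fsc_v[s - 1] - fsc_v[s])
        freq[s - 1] + frac * (freq[s] - freq[s - 1])
      }
      resolution <- 1 / f_cross
    }
  }
  list(freq = freq, fsc = fsc_v, resolution = resolution,
       zero_power = zero_power)
}

## internal: Kabsch orthogonal superposition minimizing
## sum ||R x_i + t - y_i||^2 over proper rotations
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(X - matrix(cx, nrow(X), 3, byrow = TRUE),
                 Y - matrix(cy, nrow(Y), 3, byrow = TRUE))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  list(R = R, t = cy - as.vector(R %*% cx))
}

## internal: ICP of model onto reference from a given starting rotation
icp_once <- function(model, reference, R0 = diag(3), max_iter = 100,
                     tol = 1e-8) {
  R <- R0; tv <- colMeans(reference) - as.vector(R0 %*% colMeans(model))
  last <- Inf
  for (it in seq_len(max_iter)) {
    Xt <- model %*% t(R) + matrix(tv, nrow(model), 3, byrow = TRUE)
    ## nearest reference point for each model point
    cross <- Xt %*% t(reference)
    d2 <- outer(rowSums(Xt^2), rowSums(reference^2), "+") - 2 * cross
    nn <- apply(d2, 1, which.min)
    fit <- kabsch(model, reference[nn, , drop = FALSE])
    R <- fit$R; tv <- fit$t
    err <- sqrt(mean(pmax(d2[cbind(seq_len(nrow(d2)), nn)], 0)))
    if (abs(last - err) < tol * max(err, 1e-12)) break
    last <- err
  }
  list(R = R, t = tv, err = err)
}

## internal: the 24 rotations of the octahedral group (proper signed
## permutation matrices), used as ICP restarts
octahedral_rotations <- function() {
  out <- list()
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) for (s1 in c(1, -1)) for (s2 in c(1, -1))
    for (s3 in c(1, -1)) {
      M <- matrix(0, 3, 3)
      M[1, p[1]] <- s1; M[2, p[2]] <- s2; M[3, p[3]] <- s3
      if (abs(det(M) - 1) < 1e-12) out[[length(out) + 1]] <- M
    }
  out
}

## internal: deterministic ICP starting rotations -- the octahedral group
## plus the icosahedral rotations from the binary icosahedral quaternions
## with positive scalar part, interleaving two lattices' coverage of SO(3)
alignment_start_rotations <- function() {
  starts <- octahedral_rotations()
  V <- build_600cell()$vertices
  keep <- V[V[, 1] > 1e-9, , drop = FALSE]   # one quaternion per rotation
  for (i in seq_len(nrow(keep)))
    starts[[length(starts) + 1]] <- quaternion_to_matrix(keep[i, ])
  starts
}

#' Gauge alignment of a reconstruction onto a reference
#'
#' Searches over a deterministic set of starting rotations (the octahedral
#' group plus the icosahedral rotations), each refined by ICP, for both the
#' model and its mirror image (z negated), and returns the variant
#' minimizing the nearest-neighbour RMSD to the reference. The
#' returned linear map \code{A} (rotation, or rotation times the reflection
#' when the mirror wins) and translation \code{t} satisfy
#' \code{aligned = model %*% t(A) + t}.
#'
#' @param model,reference \code{K x 3} matrices or \code{particle_cloud}s.
#' @param mirror Whether to also try the mirrored model.
#' @return List with \code{aligned}, \code{A}, \code{t}, \code{mirrored}
#'   (logical) and \code{rmsd} (reference -> aligned nearest-neighbour
#'   RMSD).
#' @export
gauge_align <- function(model, reference, mirror = TRUE) {
  X <- if (inherits(model, "particle_cloud")) model$positions else as.matrix(model)
  Y <- if (inherits(reference, "particle_cloud")) reference$positions else
    as.matrix(reference)
  S <- diag(c(1, 1, -1))
  best <- NULL
  starts <- alignment_start_rotations()
  for (m in if (mirror) c(FALSE, TRUE) else FALSE) {
    Xm <- if (m) X %*% S else X
    for (R0 in starts) {
      fit <- icp_once(Xm, Y, R0)
      Xa <- Xm %*% t(fit$R) + matrix(fit$t, nrow(Xm), 3, byrow = TRUE)
      r <- rmsd_nn(Y, Xa)
      if (is.null(best) || r < best$rmsd) {
        A <- if (m) fit$R %*% S else fit$R
        best <- list(aligned = Xa, A = A, t = fit$t, mirrored = m, rmsd = r)
      }
    }
  }
  best
}

#' Per-particle positional uncertainty from posterior samples
#'
#' All samples are superposed onto the first by ICP (proper rotations only;
#' chain samples share handedness), particle correspondence is established
#' by minimum-cost linear assignment on the inter-particle distance matrix,
#' and the per-particle spread is the RMS deviation of the matched positions
#' from their mean.
#'
#' @param samples List of \code{K x 3} matrices (equal K) or
#'   \code{particle_cloud}s.
#' @return Numeric length-K vector of spreads, ordered as the first sample's
#'   particles.
#' @export
uncertainty_icp_assign <- function(samples) {
  mats <- lapply(samples, function(s)
    if (inherits(s, "particle_cloud")) s$positions else as.matrix(s))
  if (length(mats) < 2) stop("need at least two samples")
  K <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != K)) stop("samples differ in K")
  ref <- mats[[1]]
  matched <- array(NA_real_, c(length(mats), K, 3))
  matched[1, , ] <- ref
  for (s in 2:length(mats)) {
    best <- NULL
    for (R0 in alignment_start_rotations()) {
      fit <- icp_once(mats[[s]], ref, R0)
      if (is.null(best) || fit$err < best$err) best <- fit
    }
    Xa <- mats[[s]] %*% t(best$R) + matrix(best$t, K, 3, byrow = TRUE)
    cost <- sqrt(pmax(outer(rowSums(ref^2), rowSums(Xa^2), "+") -
                        2 * ref %*% t(Xa), 0))
    perm <- as.integer(clue::solve_LSAP(cost))
    matched[s, , ] <- Xa[perm, , drop = FALSE]
  }
  mean_pos <- apply(matched, c(2, 3), mean)
  spreads <- sqrt(vapply(seq_len(K), function(k)
    mean(rowSums((matched[, k, ] -
                    matrix(mean_pos[k, ], length(mats), 3, byrow = TRUE))^2)),
    numeric(1)))
  spreads
}

#' Per-view rotation errors after gauge removal
#'
#' Given the gauge map \code{A} from \code{gauge_align(model, truth)} (so
#' \code{truth ~ A model}, i.e. \code{model ~ t(A) truth}), the estimated and
#' true rotations of view n should satisfy \code{Rhat_n t(A) = R_n} when the
#' gauge is proper, or \code{Rhat_n t(A) = S_z R_n} with \code{S_z =
#' diag(1, 1, -1)} when the mirror won (only the projected first two rows
#' are constrained by the data). Returns the geodesic angle of the residual
#' per view.
#'
#' @param est_poses,true_poses Lists of \code{view_pose}s.
#' @param A Gauge linear map from \code{\link{gauge_align}} (possibly
#'   improper).
#' @return Numeric vector of angles in radians.
#' @export
pose_rotation_errors <- function(est_poses, true_poses, A = diag(3)) {
  improper <- det(A) < 0
  Sz <- diag(c(1, 1, -1))
  vapply(seq_along(est_poses), function(n) {
    B <- quaternion_to_matrix(est_poses[[n]]$q) %*% t(A) %*%
      t(quaternion_to_matrix(true_poses[[n]]$q))
    if (improper) B <- Sz %*% B
    rotation_angle(B)
  }, numeric(1))
}
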