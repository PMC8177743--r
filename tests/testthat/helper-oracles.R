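# Independent oracles used across the suite: quadrature for Gaussian
# projections, flood fill for connected components, brute-force assignment.

# line-integral of a 3D Gaussian along the projection direction of rotation R
# at image point u (the X-ray transform, evaluated by quadrature)
line_integral_gaussian <- function(u, center, sigma, R, half = 15,
                                   n_nodes = 4001) {
  z <- seq(-half, half, length.out = n_nodes)
  h <- z[2] - z[1]
  # r = R^T (u, z): columns of R^T span the image plane and the direction
  r <- cbind(outer(rep(1, n_nodes), as.numeric(t(R) %*% c(u, 0))),
             outer(z, R[3, ]))
  pts <- r[, 1:3] + r[, 4:6]
  sum(gaussian_eval(pts, center, sigma)) * h
}

# flood-fill labeling with 4-connectivity, the reference for
# connected_components
flood_fill_labels <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1) %% nrow(mask) + 1
      j <- (cur - 1) %/% nrow(mask) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
          nb <- (jj - 1) * nrow(mask) + ii
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# exhaustive minimum-cost one-to-one assignment for small K
brute_force_assignment <- function(cost) {
  K <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(K))) {
    cc <- sum(cost[cbind(seq_len(K), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(perm = best, cost = best_cost)
}

# render a 2D equal-weight Gaussian mixture on a pixel grid (oracle for EM
# round trips), centers in 1-based pixel coordinates
render_mixture_2d <- function(centers, sigma, n) {
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    gx <- exp(-((1:n) - centers[k, 1])^2 / (2 * sigma^2))
    gy <- exp(-((1:n) - centers[k, 2])^2 / (2 * sigma^2))
    img <- img + outer(gx, gy) / (2 * pi * sigma^2)
  }
  img / nrow(centers)
}

# rotation matrix -> unit quaternion (w, x, y, z), for building test poses
matrix_to_quaternion_test <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

# tiny PDB fixture: three atoms, one of them a C-alpha
write_toy_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  O   ALA A   1      13.006   6.697  -3.147  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}
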