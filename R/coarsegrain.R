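## Reference coarse-grained models from atomic coordinates. DP-means hard
## clustering (k-means with a distance penalty that spawns new clusters)
## reduces L atoms to K particle centers; a power law predicts the effective
## particle radius for the excluded-volume prior.

#' Predict the effective particle radius
#'
#' Empirical power law \code{R = 0.92 * (L / K)^0.42} Angstrom relating the
#' particle radius to the number of atoms represented per particle, derived
#' from coarse-graining biomolecular structures at many levels.
#'
#' @param L Number of atoms in the structure.
#' @param K Number of coarse-grained particles.
#' @return Radius in Angstrom.
#' @export
predict_radius <- function(L, K) {
  if (K < 1 || L < 1) stop("L and K must be positive")
  if (K > L) warning("more particles than atoms; predicted radius < 0.92 A")
  0.92 * (L / K)^0.42
}

#' DP-means clustering
#'
#' Hard-assignment clustering minimizing \code{sum_i ||p_i - c(p_i)||^2 +
#' lambda * K}: points are assigned to their nearest center unless the
#' squared distance exceeds \code{lambda}, in which case the point spawns a
#' new center; centers are then recomputed as cluster means, and the sweep
#' repeats until assignments are stable. In \code{target_K} mode,
#' \code{lambda} is bisected (on a log scale) until the returned number of
#' clusters matches the target within 1\%.
#'
#' @param points \code{n x d} coordinate matrix.
#' @param lambda Squared-distance penalty; exactly one of \code{lambda} and
#'   \code{target_K} must be given.
#' @param target_K Desired number of clusters.
#' @param seed Optional RNG seed (controls the visiting-order shuffles).
#' @param n_restarts Number of seeded shuffles of the visiting order; the
#'   restart with the best objective is kept.
#' @param max_iter Maximum assignment sweeps per restart.
#' @return List with \code{centers} (\code{K x d}), \code{assignment},
#'   \code{objective} and \code{lambda}.
#' @export
dpmeans <- function(points, lambda = NULL, target_K = NULL, seed = NULL,
                    n_restarts = 5, max_iter = 100) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("need at least one point")
  if (is.null(lambda) == is.null(target_K))
    stop("give exactly one of lambda, target_K")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(lambda)) return(dpmeans_restarts(points, lambda, n_restarts,
                                                max_iter))
  ## bisection over log lambda for a target cluster count
  target_K <- as.integer(target_K)
  if (target_K > nrow(points)) stop("target_K exceeds number of points")
  spread <- sum(apply(points, 2, stats::var))
  lo <- 1e-8 * max(spread, 1); hi <- 100 * max(spread, 1)
  best <- NULL
  for (it in 1:60) {
    lam <- sqrt(lo * hi)
    fit <- dpmeans_restarts(points, lam, n_restarts, max_iter)
    K <- nrow(fit$centers)
    if (is.null(best) || abs(K - target_K) < abs(nrow(best$centers) - target_K))
      best <- fit
    if (abs(K - target_K) <= max(1, 0.01 * target_K) && K == target_K) break
    if (K > target_K) lo <- lam else hi <- lam
  }
  if (abs(nrow(best$centers) - target_K) > max(1, 0.01 * target_K))
    warning(sprintf("bisection reached K = %d for target %d",
                    nrow(best$centers), target_K))
  best
}

## internal: best-of-n restarts with shuffled visiting order
dpmeans_restarts <- function(points, lambda, n_restarts, max_iter) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ord <- if (r == 1) seq_len(nrow(points)) else sample.int(nrow(points))
    fit <- dpmeans_once(points[ord, , drop = FALSE], lambda, max_iter)
    fit$assignment <- fit$assignment[order(ord)]
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$lambda <- lambda
  best
}

## internal: one DP-means run, points visited in row order
dpmeans_once <- function(points, lambda, max_iter) {
  n <- nrow(points)
  centers <- points[1, , drop = FALSE]
  assign_ <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      d2 <- rowSums((centers - matrix(points[i, ], nrow(centers),
                                      ncol(points), byrow = TRUE))^2)
      j <- which.min(d2)
      if (d2[j] > lambda) {
        centers <- rbind(centers, points[i, ])
        j <- nrow(centers)
      }
      if (assign_[i] != j) { assign_[i] <- j; changed <- TRUE }
    }
    ## drop empty clusters, recompute means
    used <- sort(unique(assign_))
    centers <- t(vapply(used, function(u)
      colMeans(points[assign_ == u, , drop = FALSE]), numeric(ncol(points))))
    assign_ <- match(assign_, used)
    if (!changed && it > 1) break
  }
  obj <- sum((points - centers[assign_, , drop = FALSE])^2) +
    lambda * nrow(centers)
  list(centers = centers, assignment = assign_, objective = obj)
}
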