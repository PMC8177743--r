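## Posterior simulation. A Gibbs sweep updates, in order: per-view nuisance
## parameters (conjugate draws / Metropolis), per-view rotations (adaptive
## quaternion random-walk Metropolis, with occasional global scans over a
## 600-cell rotation grid), and all particle positions jointly (one
## Hamiltonian Monte Carlo proposal).

#' Gibbs sampler configuration
#'
#' @param n_sweeps Number of Gibbs sweeps.
#' @param K Number of particles of the model cloud (used when no initial
#'   state is supplied).
#' @param prior A \code{\link{prior_params}}.
#' @param kernel_sigma Width of the 3D rendering kernel (Angstrom); defaults
#'   to half the prior particle radius, tying kernel support to particle
#'   size.
#' @param leapfrog_steps Leapfrog steps per HMC proposal (default 10).
#' @param hmc_eps Initial HMC step size.
#' @param mh_steps Metropolis steps per view rotation per sweep (default 10).
#' @param mh_delta Initial rotation proposal step size.
#' @param adapt_up,adapt_down Multiplicative step-size adaptation factors on
#'   acceptance / rejection (1.02 / 0.98); their fixed point pins the
#'   long-run acceptance rate near 50\%.
#' @param scan_frequency Per-sweep probability of a global rotation scan over
#'   all views (default 0.1).
#' @param scan_per_view If \code{TRUE}, the Bernoulli scan trigger is drawn
#'   per view instead of once per sweep.
#' @param grid_level Subdivision level of the rotation grid used for scans
#'   (0 = 330 cells, 1 = 2,640).
#' @param adapt_burnin Sweep count after which the HMC step size is frozen
#'   and global scans are Metropolized (restoring exact detailed balance);
#'   defaults to 80\% of \code{n_sweeps}.
#' @param sample_positions,sample_rotations,sample_nuisance Block flags.
#' @param sample_shift,sample_mag Whether per-view shifts / magnifications
#'   are sampled (random-walk Metropolis); off by default.
#' @param sigma_mh_steps Metropolis steps on \code{log sigma_n} per sweep for
#'   the point-cloud model width.
#' @param shift_prior_sd Standard deviation of the zero-centered Gaussian
#'   prior on shifts.
#' @param init_radius Radius of the ball for random position initialization;
#'   \code{NULL} derives it from the data extent.
#' @param keep_every Store a chain snapshot every this many sweeps.
#' @return An object of class \code{gibbs_config}.
#' @export
gibbs_config <- function(n_sweeps = 500, K = 50, prior = prior_params(),
                         kernel_sigma = NULL,
                         leapfrog_steps = 10, hmc_eps = 0.1,
                         mh_steps = 10, mh_delta = 0.1,
                         adapt_up = 1.02, adapt_down = 0.98,
                         scan_frequency = 0.1, scan_per_view = FALSE,
                         grid_level = 0, adapt_burnin = NULL,
                         sample_positions = TRUE, sample_rotations = TRUE,
                         sample_nuisance = TRUE, sample_shift = FALSE,
                         sample_mag = FALSE, sigma_mh_steps = 5,
                         shift_prior_sd = 10, init_radius = NULL,
                         keep_every = 10) {
  if (scan_frequency < 0 || scan_frequency > 1)
    stop("scan_frequency must be in [0, 1]")
  if (n_sweeps < 1 || leapfrog_steps < 1 || mh_steps < 1)
    stop("counts must be positive")
  if (is.null(kernel_sigma)) kernel_sigma <- prior$radius / 2
  ## adaptation (and raw exploratory scans) run for most of the chain; the
  ## final fifth uses frozen step sizes and Metropolized scans, restoring
  ## exact detailed balance for the retained samples
  if (is.null(adapt_burnin)) adapt_burnin <- floor(0.8 * n_sweeps)
  structure(as.list(environment()), class = "gibbs_config")
}

## internal: one generic HMC proposal with L leapfrog steps on potential U
hmc_step <- function(x, U_fn, grad_fn, eps, L) {
  p <- array(stats::rnorm(length(x)), dim = dim(x) %||% length(x))
  U0 <- U_fn(x)
  H0 <- U0 + sum(p^2) / 2
  xn <- x
  g <- grad_fn(xn)
  ok <- all(is.finite(g))
  if (ok) {
    p <- p - eps / 2 * g
    for (l in seq_len(L)) {
      xn <- xn + eps * p
      g <- grad_fn(xn)
      if (!all(is.finite(g))) { ok <- FALSE; break }
      p <- p - eps * (if (l < L) g else g / 2)
    }
  }
  if (!ok) return(list(x = x, accept = FALSE, dH = Inf))
  H1 <- U_fn(xn) + sum(p^2) / 2
  dH <- H1 - H0
  accept <- is.finite(dH) && stats::runif(1) < exp(min(0, -dH))
  list(x = if (accept) xn else x, accept = accept, dH = dH)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## internal: joint potential over particle positions (negative conditional
## log-posterior) and its gradient
positions_potential <- function(views, state) {
  cloud <- state$cloud
  list(
    U = function(X) {
      cl <- cloud; cl$positions <- X
      ll <- 0
      for (n in seq_along(views))
        ll <- ll + view_log_likelihood(views[[n]], cl, state$poses[[n]],
                                       state$nuisances[[n]])
      -(ll + log_prior_positions(X, state$prior)$value)
    },
    grad = function(X) {
      cl <- cloud; cl$positions <- X
      g <- matrix(0, nrow(X), 3)
      for (n in seq_along(views))
        g <- g + view_position_grad(views[[n]], cl, state$poses[[n]],
                                    state$nuisances[[n]])
      -(g + log_prior_positions(X, state$prior)$grad)
    })
}

#' One HMC update of all particle positions
#'
#' Proposes new positions by leapfrog integration of Hamiltonian dynamics on
#' the negative conditional log-posterior and accepts by the Metropolis
#' criterion. The step size is multiplied by \code{adapt_up} on acceptance
#' and \code{adapt_down} on rejection while \code{adapt} is \code{TRUE}.
#'
#' @param state A posterior state (list with \code{cloud}, \code{poses},
#'   \code{nuisances}, \code{prior}, \code{hmc_eps}).
#' @param views List of data views.
#' @param config A \code{\link{gibbs_config}}.
#' @param adapt Whether to adapt the step size.
#' @return The updated state, with an \code{accept} flag in
#'   \code{state$last_hmc_accept}.
#' @export
hmc_positions <- function(state, views, config, adapt = TRUE) {
  pot <- positions_potential(views, state)
  res <- hmc_step(state$cloud$positions, pot$U, pot$grad,
                  eps = state$hmc_eps, L = config$leapfrog_steps)
  state$cloud$positions <- res$x
  if (adapt)
    state$hmc_eps <- state$hmc_eps *
      if (res$accept) config$adapt_up else config$adapt_down
  state$last_hmc_accept <- res$accept
  state
}

#' Adaptive Metropolis update of one view's rotation quaternion
#'
#' Proposes \code{q' = normalize(q + delta * u)} with \code{u} uniform on
#' \code{[-1, 1]^4} and accepts by the rotation conditional; the step size is
#' multiplied by 1.02 on acceptance and 0.98 on rejection, whose fixed point
#' yields a long-run acceptance rate near 50\%.
#'
#' @param state Posterior state.
#' @param views List of data views.
#' @param i View index.
#' @param n_steps Number of Metropolis steps.
#' @param config A \code{\link{gibbs_config}}.
#' @return Updated state; \code{state$last_mh_accept[i]} holds the fraction
#'   of accepted steps.
#' @export
mh_rotation <- function(state, views, i, n_steps = 10,
                        config = gibbs_config()) {
  pose <- state$poses[[i]]
  q <- pose$q
  delta <- state$mh_delta[i]
  lp <- rotation_conditional_logpdf(q, views[[i]], state$cloud,
                                    state$nuisances[[i]], pose)
  n_acc <- 0
  for (s in seq_len(n_steps)) {
    qp <- q + delta * stats::runif(4, -1, 1)
    qp <- qp / sqrt(sum(qp^2))
    lpp <- rotation_conditional_logpdf(qp, views[[i]], state$cloud,
                                       state$nuisances[[i]], pose)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      q <- qp; lp <- lpp; n_acc <- n_acc + 1
      delta <- delta * config$adapt_up
    } else delta <- delta * config$adapt_down
  }
  state$poses[[i]]$q <- q
  state$mh_delta[i] <- delta
  state$last_mh_accept[i] <- n_acc / n_steps
  state
}

#' Global rotation scan for one view
#'
#' Evaluates the rotation conditional at every grid quaternion, forms the
#' normalized discrete distribution by log-sum-exp and draws one quaternion,
#' to be refined by subsequent local Metropolis steps. With
#' \code{metropolize = TRUE} the draw is used as an independence proposal and
#' accepted with probability \code{min(1, exp(lp_cell(q) - lp(q)))}, where
#' \code{lp_cell(q)} is the grid value of the current pose's cell: exact for
#' cell-center proposals, so the move leaves the rotation conditional
#' invariant instead of clamping refined poses back onto the grid. A raw
#' (always-accepted) scan is an exploration move suitable for burn-in.
#'
#' @param state Posterior state.
#' @param views List of data views.
#' @param i View index.
#' @param grid A \code{\link{hemisphere_grid}} (possibly subdivided).
#' @param metropolize Apply the independence-sampler correction.
#' @return Updated state with the sampled quaternion in pose \code{i}.
#' @export
global_rotation_scan <- function(state, views, i, grid, metropolize = FALSE) {
  Q <- grid$quaternions
  lp <- scan_logpdfs(views[[i]], state$cloud, state$nuisances[[i]],
                     state$poses[[i]], Q)
  if (!any(is.finite(lp))) stop("all grid rotations have zero posterior mass")
  lp[!is.finite(lp)] <- -Inf
  mx <- max(lp)
  prob <- exp(lp - mx)
  j <- sample.int(nrow(Q), 1, prob = prob)
  if (metropolize) {
    q_cur <- state$poses[[i]]$q
    lp_cur <- rotation_conditional_logpdf(q_cur, views[[i]], state$cloud,
                                          state$nuisances[[i]],
                                          state$poses[[i]])
    cell <- which.max(abs(Q %*% q_cur))
    if (log(stats::runif(1)) >= lp[cell] - lp_cur) return(state)
  }
  state$poses[[i]]$q <- Q[j, ]
  state
}

## internal: rotation-conditional log-density at every quaternion of a scan
## grid. Point-cloud views are evaluated in blocks with one matrix product
## for all projected centers; image views fall back to per-quaternion calls.
scan_logpdfs <- function(view, cloud, nuisance, pose, Q) {
  G <- nrow(Q)
  if (inherits(view, "image_view"))
    return(vapply(seq_len(G), function(j)
      rotation_conditional_logpdf(Q[j, ], view, cloud, nuisance, pose),
      numeric(1)))
  X <- cloud$positions
  K <- nrow(X)
  y <- view$points
  s2 <- nuisance$sigma^2
  ## first two rotation-matrix rows for every grid quaternion at once
  w <- Q[, 1]; qx <- Q[, 2]; qy <- Q[, 3]; qz <- Q[, 4]
  P2 <- matrix(0, 2 * G, 3)
  odd <- seq(1, 2 * G, 2)
  P2[odd, 1] <- 1 - 2 * (qy^2 + qz^2)
  P2[odd, 2] <- 2 * (qx * qy - w * qz)
  P2[odd, 3] <- 2 * (qx * qz + w * qy)
  P2[odd + 1, 1] <- 2 * (qx * qy + w * qz)
  P2[odd + 1, 2] <- 1 - 2 * (qx^2 + qz^2)
  P2[odd + 1, 3] <- 2 * (qy * qz - w * qx)
  C <- P2 %*% t(X) * pose$mag          # 2G x K projected centers
  cx <- C[seq(1, 2 * G, 2), , drop = FALSE] + pose$shift[1]   # G x K
  cy <- C[seq(2, 2 * G, 2), , drop = FALSE] + pose$shift[2]
  cpp_scan_loglik(y, cx, cy, s2, LOG_FLOOR)
}

#' Gibbs update of one view's nuisance parameters
#'
#' Image model: \code{(alpha, gamma)} drawn jointly from their bivariate
#' normal conditional (flat priors; a linear-Gaussian regression of the image
#' on the rendered mixture basis), then \code{tau ~ Gamma(M/2, SSR/2)} under
#' a Jeffreys prior. Point-cloud model: the per-view width \code{sigma_n} is
#' updated by adaptive Metropolis on \code{log sigma_n} (the Jeffreys prior
#' on the precision is flat in \code{log sigma}). Shift and magnification,
#' when enabled, move by adaptive random-walk Metropolis.
#'
#' @param state Posterior state.
#' @param views List of data views.
#' @param i View index.
#' @param config A \code{\link{gibbs_config}}.
#' @return Updated state.
#' @export
gibbs_nuisance <- function(state, views, i, config = gibbs_config()) {
  view <- views[[i]]
  if (inherits(view, "image_view")) {
    nu <- state$nuisances[[i]]
    basis <- render_projection_image(state$cloud, state$poses[[i]],
                                     view$grid, alpha = 0, gamma = 1)
    b <- as.vector(basis$intensities)
    g <- as.vector(view$intensities)
    M <- length(g)
    if (stats::sd(b) < 1e-12) {
      warning("constant rendered image; skipping scale update")
      nu$alpha <- stats::rnorm(1, mean(g) - nu$gamma * mean(b),
                               1 / sqrt(nu$tau * M))
    } else {
      X <- cbind(1, b)
      XtX <- crossprod(X)
      coef_hat <- solve(XtX, crossprod(X, g))
      S <- chol(solve(XtX) / nu$tau)
      coef <- coef_hat + t(S) %*% stats::rnorm(2)
      nu$alpha <- coef[1]; nu$gamma <- coef[2]
    }
    ssr <- max(sum((g - nu$alpha - nu$gamma * b)^2), 1e-12)
    nu$tau <- stats::rgamma(1, shape = M / 2, rate = ssr / 2)
    state$nuisances[[i]] <- nu
  } else {
    ## width sigma_n: adaptive MH on log sigma, flat prior in log sigma
    for (s in seq_len(config$sigma_mh_steps)) {
      nu <- state$nuisances[[i]]
      lp <- cloud_log_likelihood(view, state$cloud, state$poses[[i]], nu)
      nup <- nu
      nup$sigma <- exp(log(nu$sigma) + state$sigma_delta[i] * stats::rnorm(1))
      lpp <- cloud_log_likelihood(view, state$cloud, state$poses[[i]], nup)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        state$nuisances[[i]] <- nup
        state$sigma_delta[i] <- state$sigma_delta[i] * config$adapt_up
      } else state$sigma_delta[i] <- state$sigma_delta[i] * config$adapt_down
    }
  }
  if (config$sample_shift)
    state <- mh_pose_param(state, views, i, "shift", config)
  if (config$sample_mag)
    state <- mh_pose_param(state, views, i, "mag", config)
  state
}

## internal: random-walk MH on a pose parameter (shift, or log magnification)
mh_pose_param <- function(state, views, i, what, config) {
  pose <- state$poses[[i]]
  nu <- state$nuisances[[i]]
  logpost <- function(p) {
    ll <- view_log_likelihood(views[[i]], state$cloud, p, nu)
    ll - sum(p$shift^2) / (2 * config$shift_prior_sd^2)
  }
  lp <- logpost(pose)
  pp <- pose
  if (what == "shift") {
    key <- "shift_delta"
    pp$shift <- pose$shift + state$shift_delta[i] * stats::rnorm(2)
  } else {
    key <- "mag_delta"
    pp$mag <- exp(log(pose$mag) + state$mag_delta[i] * stats::rnorm(1))
  }
  lpp <- logpost(pp)
  if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
    state$poses[[i]] <- pp
    state[[key]][i] <- state[[key]][i] * config$adapt_up
  } else state[[key]][i] <- state[[key]][i] * config$adapt_down
  state
}

## internal: joint log-posterior of the current state
state_log_posterior <- function(state, views) {
  ll <- 0
  for (n in seq_along(views))
    ll <- ll + view_log_likelihood(views[[n]], state$cloud, state$poses[[n]],
                                   state$nuisances[[n]])
  ll + log_prior_positions(state$cloud$positions, state$prior)$value
}

## internal: data extent (max absolute coordinate) of a list of views
data_extent <- function(views) {
  mx <- 0
  for (v in views)
    mx <- max(mx, if (inherits(v, "image_view"))
      max(abs(v$grid$coords)) else max(abs(v$points)))
  mx
}

#' Random initial posterior state
#'
#' Positions drawn uniformly in a ball ("spherical random structure"),
#' quaternions uniform on the 3-sphere, unit magnifications, zero shifts.
#'
#' @param views List of data views.
#' @param config A \code{\link{gibbs_config}}.
#' @return A posterior-state list.
#' @export
init_state <- function(views, config) {
  N <- length(views)
  r0 <- config$init_radius %||% (0.5 * data_extent(views))
  K <- config$K
  ## uniform in a ball of radius r0
  X <- matrix(stats::rnorm(3 * K), K, 3)
  X <- X / sqrt(rowSums(X^2)) * r0 * stats::runif(K)^(1 / 3)
  prior <- config$prior
  if (!is.finite(prior$box_halfwidth))
    prior$box_halfwidth <- 1.5 * data_extent(views)
  ## point-cloud widths start overdispersed (a third of the data extent):
  ## early rotation conditionals stay flat and mobile, and the width
  ## Metropolis updates shrink sigma_n as the fit forms
  sig0 <- max(data_extent(views) / 3, config$kernel_sigma)
  nuis <- lapply(seq_len(N), function(n) {
    v <- views[[n]]
    if (inherits(v, "image_view"))
      view_nuisance(alpha = mean(v$intensities), gamma = 1,
                    tau = 1 / max(stats::var(as.vector(v$intensities)), 1e-8))
    else view_nuisance(sigma = sig0)
  })
  qs <- random_quaternion(N)
  list(cloud = particle_cloud(X, sig0),
       poses = lapply(seq_len(N), function(n) view_pose(qs[n, ])),
       nuisances = nuis, prior = prior,
       hmc_eps = config$hmc_eps,
       mh_delta = rep(config$mh_delta, N),
       sigma_delta = rep(0.05, N),
       shift_delta = rep(0.5, N),
       mag_delta = rep(0.02, N),
       last_mh_accept = rep(NA_real_, N))
}

#' Run the full Gibbs sampler
#'
#' Per sweep: nuisance parameters of all views, then rotations (with
#' probability \code{scan_frequency} a global grid scan precedes the local
#' Metropolis refinement), then one HMC update of all particle positions.
#' Fully deterministic given the seed.
#'
#' @param views List of \code{image_view} or \code{point_cloud_view} objects.
#' @param config A \code{\link{gibbs_config}}.
#' @param init Optional initial state (as returned by \code{init_state}); by
#'   default a random state is drawn (re-drawn, up to 20 times, if its
#'   posterior is not finite).
#' @param seed Optional RNG seed (\code{set.seed} is called when non-null).
#' @param verbose Print one line per 50 sweeps.
#' @return List with \code{state} (final), \code{chain} (snapshots of
#'   positions and quaternions), and \code{diagnostics} (per-sweep data
#'   frame: log-posterior, acceptance rates, step sizes).
#' @export
run_gibbs <- function(views, config = gibbs_config(), init = NULL,
                      seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  state <- init
  if (is.null(state)) {
    for (try in 1:20) {
      state <- init_state(views, config)
      if (is.finite(state_log_posterior(state, views))) break
      if (try == 20) stop("could not find a finite-posterior initial state")
    }
  }
  N <- length(views)
  grid <- NULL
  if (config$sample_rotations && config$scan_frequency > 0) {
    grid <- hemisphere_grid()
    if (config$grid_level > 0) grid <- subdivide(grid, config$grid_level)
  }
  diag_rows <- vector("list", config$n_sweeps)
  chain <- list()
  for (sweep in seq_len(config$n_sweeps)) {
    if (config$sample_nuisance)
      for (i in seq_len(N)) state <- gibbs_nuisance(state, views, i, config)
    if (config$sample_rotations) {
      scan_all <- !config$scan_per_view &&
        stats::runif(1) < config$scan_frequency
      for (i in seq_len(N)) {
        do_scan <- scan_all || (config$scan_per_view &&
                                  stats::runif(1) < config$scan_frequency)
        if (do_scan)
          state <- global_rotation_scan(state, views, i, grid,
                                        metropolize =
                                          sweep > config$adapt_burnin)
        state <- mh_rotation(state, views, i, config$mh_steps, config)
      }
    }
    if (config$sample_positions)
      state <- hmc_positions(state, views, config,
                             adapt = sweep <= config$adapt_burnin)
    lp <- state_log_posterior(state, views)
    diag_rows[[sweep]] <- data.frame(
      sweep = sweep, log_posterior = lp,
      hmc_accept = state$last_hmc_accept %||% NA,
      hmc_eps = state$hmc_eps,
      mh_accept = mean(state$last_mh_accept),
      mh_delta = mean(state$mh_delta))
    if (sweep %% config$keep_every == 0 || sweep == config$n_sweeps)
      chain[[length(chain) + 1]] <- list(
        sweep = sweep,
        positions = state$cloud$positions,
        quaternions = t(vapply(state$poses, function(p) p$q, numeric(4))))
    if (verbose && sweep %% 50 == 0)
      message(sprintf("sweep %d  logpost %.2f  eps %.3g", sweep, lp,
                      state$hmc_eps))
  }
  list(state = state, chain = chain,
       diagnostics = do.call(rbind, diag_rows))
}

#' Run several independent Gibbs chains and keep the best
#'
#' The joint posterior over structure and poses is multimodal; independent
#' restarts from random initializations are the standard guard against a
#' chain settling in a subordinate mode. Chains are compared by their own
#' average log-posterior over the final sweeps (an internal criterion; no
#' reference structure is consulted).
#'
#' @param views List of data views.
#' @param config A \code{\link{gibbs_config}}.
#' @param n_chains Number of independent chains.
#' @param seed Base seed; chain \code{c} runs with \code{seed + c - 1}.
#' @param verbose Report per-chain summaries.
#' @return The \code{\link{run_gibbs}} result of the selected chain, with
#'   \code{chain_logposts} (the per-chain selection scores) attached.
#' @export
run_gibbs_restarts <- function(views, config = gibbs_config(), n_chains = 3,
                               seed = 1, verbose = FALSE) {
  best <- NULL
  scores <- numeric(n_chains)
  for (cc in seq_len(n_chains)) {
    res <- run_gibbs(views, config, seed = seed + cc - 1)
    lp <- res$diagnostics$log_posterior
    scores[cc] <- mean(utils::tail(lp, max(1, config$n_sweeps %/% 10)))
    if (verbose)
      message(sprintf("chain %d: final log-posterior %.2f", cc, scores[cc]))
    if (is.null(best) || scores[cc] > max(scores[seq_len(cc - 1)]))
      best <- res
  }
  best$chain_logposts <- scores
  best
}
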