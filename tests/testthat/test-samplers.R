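# MCMC kernels: HMC, adaptive quaternion Metropolis, global rotation scans,
# conjugate nuisance updates, and the Gibbs orchestration.

test_that("HMC conserves energy as the step size vanishes", {
  set.seed(20)
  U <- function(x) sum(x^2) / 2
  gr <- function(x) x
  x <- rnorm(5)
  dHs <- replicate(100, rtomo:::hmc_step(x, U, gr, eps = 1e-3, L = 10)$dH)
  expect_lt(max(abs(dHs)), 1e-4)
})

test_that("HMC samples a standard normal with correct moments", {
  set.seed(21)
  U <- function(x) sum(x^2) / 2
  gr <- function(x) x
  x <- rnorm(1)
  draws <- numeric(5000)
  for (i in seq_along(draws)) {
    x <- rtomo:::hmc_step(x, U, gr, eps = 0.5, L = 10)$x
    draws[i] <- x
  }
  se <- sd(draws) / sqrt(length(draws) / 10)   # crude ESS deflation
  expect_lt(abs(mean(draws)), 3 * se)
  expect_equal(var(draws), 1, tolerance = 0.1)
  # distributional check against the exact target
  ks <- suppressWarnings(ks.test(draws[seq(1, 5000, by = 5)], pnorm))
  expect_gt(ks$p.value, 0.01)
})

test_that("rotation MH accepts everything on a flat target", {
  # empty model: the image likelihood is rotation-independent
  view <- image_view(matrix(rnorm(64, sd = 0.1), 8, 8))
  config <- gibbs_config(n_sweeps = 2, K = 2, prior = prior_params(radius = 1))
  state <- list(cloud = NULL,
                poses = list(view_pose(c(1, 0, 0, 0))),
                nuisances = list(rtomo:::view_nuisance(alpha = 0, gamma = 1,
                                                       tau = 1)),
                mh_delta = 0.1, last_mh_accept = NA_real_)
  set.seed(22)
  state <- mh_rotation(state, list(view), 1, n_steps = 25, config)
  expect_equal(state$last_mh_accept, 1)
  expect_equal(state$mh_delta, 0.1 * 1.02^25)
})

test_that("step-size adaptation settles at its analytic acceptance rate", {
  # fixed point of E[d ln delta] = 0: p ln 1.02 + (1-p) ln 0.98 = 0
  p_star <- log(1 / 0.98) / log(1.02 / 0.98)
  expect_equal(p_star, 0.505, tolerance = 1e-3)
  set.seed(23)
  cl <- make_cloud("asymmetric-blob", K = 10, scale = 20, seed = 3)
  sim <- simulate_views(cl, 1, mode = "points", M = 30, sigma_n = 2,
                        seed = 24)
  config <- gibbs_config(n_sweeps = 2, K = 10, prior = prior_params(radius = 4))
  state <- list(cloud = cl, poses = sim$poses,
                nuisances = list(rtomo:::view_nuisance(sigma = 2)),
                mh_delta = 0.1, last_mh_accept = NA_real_)
  accept <- numeric(400)
  for (b in 1:400) {   # 10^4 steps in blocks of 25
    state <- mh_rotation(state, sim$views, 1, n_steps = 25, config)
    accept[b] <- state$last_mh_accept
  }
  rate <- mean(accept[201:400])
  expect_equal(rate, p_star, tolerance = 0.04)
  # delta trace is stable: log-step drift over the last half is ~0
  expect_lt(abs(mean(accept[201:400]) - p_star), 0.04)
})

test_that("global scan lands near the truth for a single informative view", {
  set.seed(25)
  cl <- make_cloud("asymmetric-blob", K = 10, scale = 20, seed = 3)
  grid <- subdivide(hemisphere_grid(), 1)
  # covering radius of the level-1 grid (sampled)
  qs <- random_quaternion(500)
  cover <- max(2 * acos(pmin(apply(abs(qs %*% t(grid$quaternions)), 1, max),
                             1)))
  config <- gibbs_config(n_sweeps = 2, K = 10, prior = prior_params(radius = 4))
  hit <- logical(100)
  for (r in 1:100) {
    q_true <- random_quaternion(1)[1, ]
    pts <- project_cloud(cl, view_pose(q_true))$centers
    state <- list(cloud = cl, poses = list(view_pose()),
                  nuisances = list(rtomo:::view_nuisance(sigma = 1)),
                  mh_delta = 0.1, last_mh_accept = NA_real_)
    views <- list(point_cloud_view(pts))
    state <- global_rotation_scan(state, views, 1, grid)
    state <- mh_rotation(state, views, 1, n_steps = 10, config)
    hit[r] <- quaternion_angle(state$poses[[1]]$q, q_true) <= cover
  }
  expect_gte(mean(hit), 0.95)
})

test_that("global scan samples uniformly when the likelihood is flat", {
  # a single particle at the origin projects identically under any rotation
  cl <- particle_cloud(matrix(0, 1, 3), sigma = 1)
  v <- point_cloud_view(matrix(rnorm(10), 5, 2))
  grid <- hemisphere_grid()
  lp <- rtomo:::scan_logpdfs(v, cl, rtomo:::view_nuisance(sigma = 2),
                             view_pose(), grid$quaternions)
  expect_lt(diff(range(lp)), 1e-9)
  set.seed(26)
  n <- 2e4
  state <- list(cloud = cl, poses = list(view_pose()),
                nuisances = list(rtomo:::view_nuisance(sigma = 2)))
  counts <- integer(330)
  for (i in 1:n) {
    state <- global_rotation_scan(state, list(v), 1, grid)
    # signed dot product: antipodal equatorial twins are distinct cells
    j <- which.max(grid$quaternions %*% state$poses[[1]]$q)
    counts[j] <- counts[j] + 1L
  }
  chi <- sum((counts - n / 330)^2 / (n / 330))
  expect_lt(chi, qchisq(0.99, df = 329))
})

test_that("conjugate nuisance updates recover known image parameters", {
  set.seed(27)
  cl <- make_cloud("asymmetric-blob", K = 8, scale = 15, seed = 5)
  cl$sigma <- 4
  pose <- view_pose(random_quaternion(1)[1, ])
  grid <- image_grid(24, 2)
  clean <- render_projection_image(cl, pose, grid, alpha = 1, gamma = 2)
  tau_true <- 1e4
  img <- image_view(clean$intensities +
                      matrix(rnorm(24^2, sd = 1 / sqrt(tau_true)), 24, 24),
                    2)
  config <- gibbs_config(n_sweeps = 2, K = 8, prior = prior_params(radius = 2))
  state <- list(cloud = cl, poses = list(pose),
                nuisances = list(rtomo:::view_nuisance(alpha = 0, gamma = 1,
                                                       tau = 1)))
  draws <- matrix(NA_real_, 500, 3)
  for (i in 1:500) {
    state <- gibbs_nuisance(state, list(img), 1, config)
    nu <- state$nuisances[[1]]
    draws[i, ] <- c(nu$alpha, nu$gamma, nu$tau)
  }
  keep <- draws[101:500, ]
  expect_lt(abs(mean(keep[, 1]) - 1), 3 * sd(keep[, 1]) + 1e-3)
  expect_lt(abs(mean(keep[, 2]) - 2), 3 * sd(keep[, 2]) + 1e-3)
  # precision posterior concentrates near the generating value
  expect_equal(mean(keep[, 3]), tau_true, tolerance = 0.3 * tau_true)
})

test_that("magnification stays fixed when its sampling is disabled", {
  cl <- make_cloud("asymmetric-blob", K = 6, scale = 15, seed = 7)
  sim <- simulate_views(cl, 2, mode = "points", M = 20, sigma_n = 2, seed = 8)
  config <- gibbs_config(n_sweeps = 2, K = 6, prior = prior_params(radius = 4),
                         sample_mag = FALSE, sample_shift = FALSE)
  set.seed(30)
  state <- init_state(sim$views, config)
  state <- gibbs_nuisance(state, sim$views, 1, config)
  expect_identical(state$poses[[1]]$mag, 1)
  expect_identical(state$poses[[1]]$shift, c(0, 0))
})

test_that("seeded Gibbs runs are exactly reproducible", {
  cl <- make_cloud("asymmetric-blob", K = 6, scale = 15, seed = 7)
  sim <- simulate_views(cl, 4, mode = "points", M = 30, sigma_n = 2,
                        seed = 8)
  config <- gibbs_config(n_sweeps = 8, K = 6,
                         prior = prior_params(radius = 4), grid_level = 0,
                         keep_every = 4)
  r1 <- run_gibbs(sim$views, config, seed = 99)
  r2 <- run_gibbs(sim$views, config, seed = 99)
  expect_identical(r1$state$cloud$positions, r2$state$cloud$positions)
  expect_identical(r1$chain[[length(r1$chain)]]$quaternions,
                   r2$chain[[length(r2$chain)]]$quaternions)
  expect_identical(r1$diagnostics$log_posterior, r2$diagnostics$log_posterior)
})

test_that("the Boltzmann prior enforces fluid-like particle separation", {
  # same data, prior on vs off: excluded volume keeps minimum pair
  # distances near the particle diameter without hurting the fit
  cl <- make_cloud("asymmetric-blob", K = 12, scale = 20, seed = 9)
  sim <- simulate_views(cl, 10, mode = "points", M = 60, sigma_n = 2,
                        seed = 10)
  run <- function(beta) {
    config <- gibbs_config(n_sweeps = 150, K = 12, hmc_eps = 0.1,
                           prior = prior_params(beta = beta, radius = 4,
                                                alpha_rg = 10),
                           scan_frequency = 0.2, grid_level = 1)
    res <- run_gibbs(sim$views, config, seed = 101)
    min(dist(res$state$cloud$positions))
  }
  d_on <- run(175)
  d_off <- run(0)
  expect_gt(d_on, d_off)
  expect_gt(d_on, 4)   # near the particle diameter 2R = 8, well above 0
})
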