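# Likelihoods, priors and their gradients.

test_that("image log-likelihood matches its closed forms", {
  grid <- image_grid(8, 1)
  g <- matrix(rnorm(64), 8, 8)
  nu <- rtomo:::view_nuisance(alpha = 0, gamma = 1, tau = 2.5)
  # zero residuals: likelihood reduces to the normalization term
  view0 <- image_view(matrix(0.4, 8, 8))
  nu0 <- rtomo:::view_nuisance(alpha = 0.4, gamma = 1, tau = 2.5)
  expect_equal(image_log_likelihood(view0, NULL, view_pose(), nu0),
               64 / 2 * log(2.5 / (2 * pi)))
  # empty model with alpha = mean: Gaussian log-density of centered data
  view <- image_view(g)
  num <- rtomo:::view_nuisance(alpha = mean(g), gamma = 1, tau = 2.5)
  expect_equal(image_log_likelihood(view, NULL, view_pose(), num),
               sum(dnorm(g, mean(g), 1 / sqrt(2.5), log = TRUE)))
})

test_that("cloud log-likelihood matches closed forms and a direct sum", {
  cl1 <- particle_cloud(rbind(c(0, 0, 0)), sigma = 1)
  nu <- rtomo:::view_nuisance(sigma = 1.5)
  v1 <- point_cloud_view(rbind(c(0, 0)))
  expect_equal(cloud_log_likelihood(v1, cl1, view_pose(), nu),
               -log(2 * pi * 1.5^2))
  # two symmetric kernels, equidistant point: mixture weights cancel
  cl2 <- particle_cloud(rbind(c(-1, 0, 0), c(1, 0, 0)), sigma = 1)
  v2 <- point_cloud_view(rbind(c(0, 0.7)))
  d2 <- 1 + 0.49
  expect_equal(cloud_log_likelihood(v2, cl2, view_pose(), nu),
               log(exp(-d2 / (2 * 1.5^2)) / (2 * pi * 1.5^2)))
  # brute-force double loop on a 5 x 7 toy
  set.seed(10)
  cl <- particle_cloud(matrix(rnorm(15), 5, 3), sigma = 1)
  pose <- view_pose(random_quaternion(1)[1, ], shift = c(0.3, -0.1),
                    mag = 1.2)
  y <- matrix(rnorm(14), 7, 2)
  ctr <- project_cloud(cl, pose)$centers
  ll_brute <- 0
  for (m in 1:7) {
    s <- 0
    for (k in 1:5)
      s <- s + exp(-sum((y[m, ] - ctr[k, ])^2) / (2 * nu$sigma^2)) /
        (2 * pi * nu$sigma^2)
    ll_brute <- ll_brute + log(s / 5)
  }
  expect_equal(cloud_log_likelihood(point_cloud_view(y), cl, pose, nu),
               ll_brute, tolerance = 1e-10)
})

test_that("position gradients match central finite differences", {
  set.seed(12)
  cl <- particle_cloud(matrix(rnorm(9) * 3, 3, 3), sigma = 1.2)
  pose <- view_pose(random_quaternion(1)[1, ], shift = c(0.5, -1), mag = 1.1)
  h <- 1e-5
  fd_check <- function(f, grad, cloud) {
    fd <- matrix(0, nrow(cloud$positions), 3)
    for (k in seq_len(nrow(cloud$positions))) for (j in 1:3) {
      cp <- cloud; cp$positions[k, j] <- cp$positions[k, j] + h
      cm <- cloud; cm$positions[k, j] <- cm$positions[k, j] - h
      fd[k, j] <- (f(cp) - f(cm)) / (2 * h)
    }
    expect_lt(max(abs(grad - fd)) / max(abs(fd)), 1e-4)
  }
  nu <- rtomo:::view_nuisance(sigma = 1.5)
  vc <- point_cloud_view(matrix(rnorm(16) * 4, 8, 2))
  fd_check(function(c_) cloud_log_likelihood(vc, c_, pose, nu),
           rtomo:::cloud_position_grad(vc, cl, pose, nu), cl)
  nui <- rtomo:::view_nuisance(alpha = 0.05, gamma = 0.8, tau = 30)
  vi <- image_view(matrix(rnorm(24 * 24, sd = 0.1), 24, 24))
  fd_check(function(c_) image_log_likelihood(vi, c_, pose, nui),
           rtomo:::image_position_grad(vi, cl, pose, nui), cl)
})

test_that("quartic repulsion takes its closed-form values", {
  R <- 2
  e <- function(d) repulsion_energy(rbind(c(0, 0, 0), c(d, 0, 0)), R)$energy
  expect_equal(e(2 * R), 0)
  expect_equal(e(0), 1)
  expect_equal(e(R), 0.0625)
  expect_equal(e(2 * R + 0.1), 0)
  # gradient continuous at the cutoff
  g_in <- repulsion_energy(rbind(c(0, 0, 0), c(2 * R - 1e-6, 0, 0)), R)$grad
  expect_lt(max(abs(g_in)), 1e-12)
})

test_that("position log-prior and gradient agree with finite differences", {
  pr <- prior_params(beta = 175, radius = 3, alpha_rg = 10,
                     box_halfwidth = 12, wall_width = 2)
  expect_equal(log_prior_positions(matrix(c(0, 0, 0), 1, 3),
                                   prior_params(beta = 0, alpha_rg = 0,
                                                radius = 1))$value, 0)
  set.seed(13)
  h <- 1e-5
  for (rep in 1:5) {
    X <- matrix(rnorm(60) * 6, 20, 3)
    lp <- log_prior_positions(X, pr)
    fd <- matrix(0, 20, 3)
    for (k in 1:20) for (j in 1:3) {
      Xp <- X; Xp[k, j] <- Xp[k, j] + h
      Xm <- X; Xm[k, j] <- Xm[k, j] - h
      fd[k, j] <- (log_prior_positions(Xp, pr)$value -
                     log_prior_positions(Xm, pr)$value) / (2 * h)
    }
    expect_lt(max(abs(lp$grad - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("likelihoods are invariant under particle relabeling and gauge", {
  set.seed(14)
  cl <- particle_cloud(matrix(rnorm(24) * 3, 8, 3), sigma = 1)
  pose <- view_pose(random_quaternion(1)[1, ])
  nu <- rtomo:::view_nuisance(sigma = 1.3, alpha = 0, gamma = 1, tau = 10)
  vc <- point_cloud_view(matrix(rnorm(20) * 3, 10, 2))
  vi <- image_view(matrix(rnorm(16 * 16, sd = .1), 16, 16))
  perm <- sample(8)
  clp <- particle_cloud(cl$positions[perm, ], cl$sigma)
  expect_equal(cloud_log_likelihood(vc, cl, pose, nu),
               cloud_log_likelihood(vc, clp, pose, nu))
  expect_equal(image_log_likelihood(vi, cl, pose, nu),
               image_log_likelihood(vi, clp, pose, nu))
  # gauge: x -> Qx with R -> R Q^T leaves the likelihood unchanged
  for (rep in 1:5) {
    Q <- quaternion_to_matrix(random_quaternion(1)[1, ])
    clq <- particle_cloud(cl$positions %*% t(Q), cl$sigma)
    Rg <- quaternion_to_matrix(pose$q) %*% t(Q)
    # pose with rotation R Q^T, via the matrix directly
    ctr_a <- project_cloud(cl, pose)$centers
    ctr_b <- (clq$positions %*% t(Rg))[, 1:2]
    expect_equal(ctr_a, ctr_b, tolerance = 1e-10)
    expect_equal(cloud_log_likelihood(vc, cl, pose, nu),
                 rtomo:::cpp_cloud_loglik(vc$points, ctr_b, nu$sigma^2,
                                          -745), tolerance = 1e-10)
  }
})

test_that("rotation conditional peaks at the true orientation", {
  set.seed(15)
  cl <- make_cloud("asymmetric-blob", K = 10, scale = 20, seed = 3)
  q_true <- random_quaternion(1)[1, ]
  sim <- simulate_views(cl, 1, mode = "points", M = 200, sigma_n = 1,
                        seed = 16)
  sim$views[[1]] <- point_cloud_view(
    project_cloud(cl, view_pose(q_true))$centers)  # noiseless, at truth
  nu <- rtomo:::view_nuisance(sigma = 1)
  lp_true <- rotation_conditional_logpdf(q_true, sim$views[[1]], cl, nu)
  # invariance under q -> -q, and equality with the likelihood
  expect_identical(lp_true,
                   rotation_conditional_logpdf(-q_true, sim$views[[1]], cl,
                                               nu))
  expect_identical(lp_true,
                   cloud_log_likelihood(sim$views[[1]], cl,
                                        view_pose(q_true), nu))
  qr <- random_quaternion(1000)
  lps <- vapply(asplit(qr, 1), function(q)
    rotation_conditional_logpdf(q, sim$views[[1]], cl, nu), numeric(1))
  expect_true(all(lp_true >= lps))
})
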