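# Particle-cloud model: kernel evaluation, rigid motion, closed-form X-ray
# projection, rendering.

test_that("gaussian_eval matches closed forms and normalizes", {
  expect_equal(gaussian_eval(c(0, 0), c(0, 0), 1), 1 / (2 * pi))
  expect_equal(gaussian_eval(1, 0, 1), exp(-1 / 2) / sqrt(2 * pi))
  expect_error(gaussian_eval(c(0, 0), c(0, 0), -1))
  # 3D quadrature: total mass 1
  sigma <- 0.7
  h <- 0.1
  ax <- seq(-5 * sigma, 5 * sigma, by = h)
  pts <- as.matrix(expand.grid(ax, ax, ax))
  mass <- sum(gaussian_eval(pts, c(0, 0, 0), sigma)) * h^3
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("rigid_transform is a group action on particle positions", {
  cl <- particle_cloud(rbind(c(1, 0, 0), c(0, 2, -1)), sigma = 1)
  expect_equal(rigid_transform(cl, diag(3), c(0, 0, 0))$positions,
               cl$positions)
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(rigid_transform(cl, Rz90)$positions[1, ], c(0, 1, 0))
  expect_error(rigid_transform(cl, diag(c(1, 1, -1))))
  # composition oracle: direct matrix algebra
  set.seed(1)
  R1 <- quaternion_to_matrix(random_quaternion(1)[1, ])
  R2 <- quaternion_to_matrix(random_quaternion(1)[1, ])
  t1 <- rnorm(3); t2 <- rnorm(3)
  a <- rigid_transform(rigid_transform(cl, R1, t1), R2, t2)
  b <- rigid_transform(cl, R2 %*% R1, as.numeric(R2 %*% t1) + t2)
  expect_equal(a$positions, b$positions, tolerance = 1e-10)
})

test_that("projection closure: line-integral quadrature equals the 2D form", {
  set.seed(7)
  cl <- particle_cloud(matrix(rnorm(3), 1, 3), sigma = 1.1)
  for (rep in 1:4) {
    pose <- view_pose(random_quaternion(1)[1, ])
    R <- quaternion_to_matrix(pose$q)
    pr <- project_cloud(cl, pose)
    for (j in 1:5) {
      u <- pr$centers[1, ] + rnorm(2)
      q_int <- line_integral_gaussian(u, cl$positions[1, ], cl$sigma, R)
      expect_equal(q_int, gaussian_eval(u, pr$centers[1, ], pr$sigma),
                   tolerance = 1e-6)
    }
  }
})

test_that("project_cloud drops z and respects magnification and shift", {
  cl <- particle_cloud(rbind(c(1.5, -2, 3)), sigma = 1)
  expect_equal(project_cloud(cl, view_pose())$centers[1, ], c(1.5, -2))
  # rotation mapping z to x (90 degrees about y)
  qy <- c(cos(pi / 4), 0, sin(pi / 4), 0)
  cl2 <- particle_cloud(rbind(c(0, 0, 1)), sigma = 1)
  expect_equal(project_cloud(cl2, view_pose(qy))$centers[1, ], c(1, 0),
               tolerance = 1e-12)
  pr <- project_cloud(cl, view_pose(mag = 2, shift = c(1, 1)))
  expect_equal(pr$centers[1, ], 2 * c(1.5, -2) + c(1, 1))
})

test_that("projection is equivariant under pre-rotation of the cloud", {
  set.seed(8)
  cl <- particle_cloud(matrix(rnorm(15), 5, 3), sigma = 1)
  R0 <- quaternion_to_matrix(random_quaternion(1)[1, ])
  q <- random_quaternion(1)[1, ]
  R <- quaternion_to_matrix(q)
  a <- project_cloud(rigid_transform(cl, R0), view_pose(q))$centers
  # pose rotation R %*% R0, built directly from the matrix product
  RR <- R %*% R0
  b <- (cl$positions %*% t(RR))[, 1:2]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("rendered projections conserve mass and superpose linearly", {
  grid <- image_grid(41, 0.5)
  expect_true(all(render_projection_image(NULL, view_pose(), grid,
                                          alpha = 0.3)$intensities == 0.3))
  cl <- particle_cloud(rbind(c(0, 0, 0)), sigma = 1.5)
  img <- render_projection_image(cl, view_pose(), grid)
  expect_equal(sum(img$intensities) * grid$pixel_size^2, 1, tolerance = 1e-3)
  # mixture linearity
  set.seed(2)
  X <- matrix(rnorm(9) * 2, 3, 3)
  cl3 <- particle_cloud(X, sigma = 1.5)
  pose <- view_pose(random_quaternion(1)[1, ])
  whole <- render_projection_image(cl3, pose, grid)$intensities
  parts <- Reduce(`+`, lapply(1:3, function(k)
    render_projection_image(particle_cloud(X[k, , drop = FALSE], 1.5),
                            pose, grid)$intensities))
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("render_volume conserves mass and projects consistently", {
  cl <- particle_cloud(rbind(c(0, 0, 0)), sigma = 2)
  vol <- render_volume(cl, n = 41, voxel_size = 0.5)
  i0 <- which(vol$density == max(vol$density), arr.ind = TRUE)
  expect_equal(as.integer(i0[1, ]), c(21L, 21L, 21L))
  expect_equal(sum(vol$density) * 0.5^3, 1, tolerance = 1e-3)
  # discrete X-ray: summing voxels along z matches the closed-form image
  set.seed(3)
  cl2 <- particle_cloud(matrix(rnorm(6), 2, 3), sigma = 2)
  vol2 <- render_volume(cl2, n = 41, voxel_size = 0.5)
  proj <- apply(vol2$density, c(1, 2), sum) * 0.5
  img <- render_projection_image(cl2, view_pose(), image_grid(41, 0.5))
  expect_equal(proj, img$intensities * cl2$weight,
               tolerance = 1e-3 * max(proj))
  expect_error(render_volume(cl, n = 0))
})

test_that("cloud constructors validate their invariants", {
  expect_error(particle_cloud(matrix(1, 1, 2), 1))
  expect_error(particle_cloud(matrix(1, 1, 3), -1))
  expect_error(particle_cloud(matrix(c(1, NA, 1), 1, 3), 1))
  expect_error(view_pose(c(1, 1, 0, 0)))
  cl <- particle_cloud(matrix(0, 4, 3), 1)
  expect_equal(cl$weight, 0.25)
})
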