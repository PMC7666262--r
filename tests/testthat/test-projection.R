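# projector, attenuation factors, trues model, Poisson resampling

test_that("forward projection is linear and matches the disk chord length", {
  g <- default_geometry()
  fx <- disk_volumes(radius = 100, activity = 1)
  sino <- forward_project(fx$activity, g)
  cbin <- which.min(abs(radial_centers(g)))
  expect_equal(mean(sino$values[cbin, , 1]), 200, tolerance = 0.02)
  zero <- fx$activity; zero$values[] <- 0
  expect_true(all(forward_project(zero, g)$values == 0))
  set.seed(1)
  a <- fx$activity; a$values[] <- runif(length(a$values))
  b <- fx$activity; b$values[] <- runif(length(b$values))
  ab <- a; ab$values <- a$values + b$values
  lhs <- forward_project(ab, g)$values
  rhs <- forward_project(a, g)$values + forward_project(b, g)$values
  expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-10)
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- scan_geometry(fov = 128, n_radial = 32, n_angles = 24)
  n <- 32; v <- 4
  set.seed(11)
  for (rep in 1:3) {
    x <- array(runif(n * n), c(n, n, 1))
    vol <- voxel_volume(x, c(v, v, 4),
                        c(-(n - 1) / 2 * v, -(n - 1) / 2 * v, 0), "activity")
    y <- array(runif(g$n_radial * g$n_angles), c(g$n_radial, g$n_angles, 1))
    ys <- sinogram(y, g, "trues")
    lhs <- sum(forward_project(vol, g)$values * y)
    rhs <- sum(x * back_project(ys, g, n, v)$values)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
  zs <- sinogram(array(0, c(g$n_radial, g$n_angles, 1)), g, "trues")
  expect_true(all(back_project(zs, g, n, v)$values == 0))
})

test_that("a single-bin impulse back-projects to a straight uniform ray", {
  g <- scan_geometry(fov = 128, n_radial = 32, n_angles = 24)
  y <- array(0, c(32, 24, 1))
  y[16, 1, 1] <- 1  # angle 0: ray along y at fixed x
  bp <- back_project(sinogram(y, g, "trues"), g, 32, 4)
  hit <- which(bp$values[, , 1] > 0, arr.ind = TRUE)
  expect_lte(length(unique(hit[, 1])), 2L)  # bilinear footprint
  expect_equal(length(unique(hit[, 2])), 32L)  # spans the image
  col <- bp$values[hit[1, 1], , 1]
  expect_lt(diff(range(col[col > 0])) / max(col), 1e-9)
})

test_that("attenuation factors match the closed-form water cylinder", {
  g <- default_geometry()
  fx <- disk_volumes(radius = 100, mu = 0.096)
  air <- fx$attenuation; air$values[] <- 0
  expect_true(all(attenuation_factors(air, g)$values == 1))
  acf <- attenuation_factors(fx$attenuation, g)
  cbin <- which.min(abs(radial_centers(g)))
  expect_equal(mean(acf$values[cbin, , 1]), exp(1.92), tolerance = 0.02)
  # adding material never decreases the acf
  more <- fx$attenuation
  more$values <- more$values + 0.01 * array(fx$d2 <= 50^2, dim(more$values))
  acf2 <- attenuation_factors(more, g)
  expect_true(all(acf2$values >= acf$values - 1e-12))
})

test_that("trues follow the attenuated line-integral model", {
  g <- default_geometry()
  fx <- disk_volumes()
  zero <- fx$activity; zero$values[] <- 0
  expect_true(all(simulate_trues(zero, fx$attenuation, g)$values == 0))
  air <- fx$attenuation; air$values[] <- 0
  t_noatt <- simulate_trues(fx$activity, air, g)
  expect_equal(t_noatt$values, forward_project(fx$activity, g)$values,
               tolerance = 1e-12)
  t1 <- simulate_trues(fx$activity, fx$attenuation, g, count_scale = 1)
  t2 <- simulate_trues(fx$activity, fx$attenuation, g, count_scale = 2)
  expect_equal(t2$values, 2 * t1$values, tolerance = 1e-12)
})

test_that("Poisson resampling is reproducible with correct moments", {
  g <- scan_geometry(fov = 32, n_radial = 8, n_angles = 4)
  zs <- sinogram(array(0, c(8, 4, 1)), g, "trues")
  expect_true(all(add_poisson(zs, 1)$values == 0))
  s <- sinogram(array(50, c(8, 4, 1)), g, "trues")
  expect_identical(add_poisson(s, 99)$values, add_poisson(s, 99)$values)
  draws <- vapply(seq_len(1000), function(k) add_poisson(s, k)$values[1, 1, 1],
                  numeric(1))
  expect_lt(abs(mean(draws) - 50), 3 * sqrt(50 / 1000))
  neg <- s; neg$values[1] <- -1
  expect_error(add_poisson(neg, 1), "negative")
})
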