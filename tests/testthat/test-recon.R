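# OSEM reconstruction and SUV calibration

test_that("matched noiseless data reconstruct the disk quantitatively", {
  g <- default_geometry()
  fx <- disk_volumes()
  tr <- simulate_trues(fx$activity, fx$attenuation, g)
  acf <- attenuation_factors(fx$attenuation, g)
  zeros <- build_scatter_estimate("NSC", geometry = g, n_slices = 1)
  img <- osem(tr, acf, zeros, g, recon_settings())
  interior <- fx$d2 <= 80^2
  expect_equal(mean(img$values[, , 1][interior]), 3.0, tolerance = 0.03)
  img2 <- osem(tr, acf, zeros, g, recon_settings())
  expect_identical(img$values, img2$values)  # deterministic
})

test_that("scatter exceeding the prompts drives voxels to zero", {
  g <- default_geometry()
  fx <- disk_volumes()
  tr <- simulate_trues(fx$activity, fx$attenuation, g)
  acf <- attenuation_factors(fx$attenuation, g)
  s <- build_scatter_estimate("NSC", geometry = g, n_slices = 1)
  s$sinogram$values[] <- 2 * max(tr$values)
  zerop <- sinogram(array(0, dim(tr$values)), g, "prompts")
  img <- osem(zerop, acf, s, g, recon_settings())
  expect_lt(max(img$values), 1e-6)
  # fully degenerate slice: zero prompts and zero scatter
  zeros <- build_scatter_estimate("NSC", geometry = g, n_slices = 1)
  expect_warning(img0 <- osem(zerop, acf, zeros, g, recon_settings()),
                 "degenerate")
  expect_true(all(img0$values == 0))
})

test_that("MLEM log-likelihood is non-decreasing", {
  g <- scan_geometry(fov = 128, n_radial = 32, n_angles = 24)
  fx <- disk_volumes(radius = 40, n = 32, voxel = 4)
  tr <- simulate_trues(fx$activity, fx$attenuation, g)
  tr <- add_poisson(tr, 4)
  acf <- attenuation_factors(fx$attenuation, g)
  zeros <- build_scatter_estimate("NSC", geometry = g, n_slices = 1)
  img <- osem(tr, acf, zeros, g,
              recon_settings(iterations = 8, subsets = 1),
              track_likelihood = TRUE)
  ll <- attr(img, "loglik")[, 1]
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-length(ll)])))
})

test_that("expected data match the prompts total at convergence", {
  g <- scan_geometry(fov = 128, n_radial = 32, n_angles = 24)
  fx <- disk_volumes(radius = 40, n = 32, voxel = 4)
  tr <- simulate_trues(fx$activity, fx$attenuation, g)
  acf <- attenuation_factors(fx$attenuation, g)
  zeros <- build_scatter_estimate("NSC", geometry = g, n_slices = 1)
  img <- osem(tr, acf, zeros, g, recon_settings(iterations = 20, subsets = 1))
  vol <- voxel_volume(img$values, img$voxel_size, img$origin, "activity")
  expected <- forward_project(vol, g)$values / acf$values
  expect_equal(sum(expected), sum(tr$values), tolerance = 0.01)
})

test_that("SUV calibration divides by the reference concentration", {
  v <- voxel_volume(array(3.0, c(4, 4, 2)), c(4, 4, 4), quantity = "activity")
  suv <- calibrate_suv(v, 3.0)
  expect_true(all(suv$values == 1.0))
  expect_equal(suv$quantity, "suv")
  z <- voxel_volume(array(0, c(4, 4, 2)), c(4, 4, 4), quantity = "activity")
  expect_true(all(calibrate_suv(z, 3)$values == 0))
  lum <- voxel_volume(array(150, c(2, 2, 1)), c(1, 1, 1), quantity = "activity")
  expect_true(all(calibrate_suv(lum, 3)$values == 50))
  expect_error(calibrate_suv(v, 0), "positive")
})
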