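# Monte-Carlo transport and analytic single-scatter simulation

test_that("scatter fraction arithmetic and error cases", {
  t0 <- scatter_tallies(100, 0, 200, 2, 1)
  expect_equal(scatter_fraction(t0), 0)
  expect_equal(scatter_fraction(scatter_tallies(50, 50, 200, 2, 1)), 0.5)
  expect_equal(scatter_fraction(scatter_tallies(300, 100, 500, 2, 1)), 0.25)
  expect_error(scatter_fraction(scatter_tallies(0, 0, 10, 2, 1)), "undefined")
  expect_error(scatter_tallies(100, 200, 150, 2, 1), "exceed")
})

test_that("transport without medium produces no scatter; seeds reproduce", {
  g <- default_geometry()
  fx <- disk_volumes()
  air <- fx$attenuation; air$values[] <- 0
  r <- mc_transport(fx$activity, air, g, n_decays = 2e4, seed = 5)
  expect_equal(r$tallies$n_scattered_detected, 0L)
  expect_gt(r$tallies$n_true_detected, 0L)
  r1 <- mc_transport(fx$activity, fx$attenuation, g, n_decays = 2e4, seed = 8)
  r2 <- mc_transport(fx$activity, fx$attenuation, g, n_decays = 2e4, seed = 8)
  expect_identical(r1$trues$values, r2$trues$values)
  expect_identical(r1$scatter$values, r2$scatter$values)
  expect_error(mc_transport(fx$activity, fx$attenuation, g, n_decays = 0), ">= 1")
})

test_that("scatter fraction grows with the medium's attenuation", {
  g <- default_geometry()
  fx <- disk_volumes()
  sfs <- vapply(c(0.5, 1, 2), function(sc) {
    att <- fx$attenuation; att$values <- att$values * sc
    scatter_fraction(mc_transport(fx$activity, att, g, n_decays = 1e5,
                                  seed = 21)$tallies)
  }, numeric(1))
  expect_true(all(diff(sfs) > 0))
})

test_that("scatter fraction is self-consistent against a larger run", {
  g <- default_geometry()
  fx <- disk_volumes()
  small <- mc_transport(fx$activity, fx$attenuation, g, n_decays = 5e4,
                        seed = 31)$tallies
  big <- mc_transport(fx$activity, fx$attenuation, g, n_decays = 5e5,
                      seed = 77)$tallies
  sf_s <- scatter_fraction(small); sf_b <- scatter_fraction(big)
  n_det <- small$n_true_detected + small$n_scattered_detected
  se <- sqrt(sf_b * (1 - sf_b) / n_det)
  expect_lt(abs(sf_s - sf_b), 3 * se)
})

test_that("single-scatter estimate matches the transport's order-1 tally", {
  g <- default_geometry()
  fx <- disk_volumes()
  # centred point source inside the water cylinder; full in-plane acceptance
  # so the transport's order-1 tally is pure single scatter on both sides
  pt <- fx$activity; pt$values[] <- 0; pt$values[73, 73, 1] <- 100
  mc <- mc_transport(pt, fx$attenuation, g, n_decays = 4e5,
                     max_scatter_order = 1L, axial_acceptance = 1, seed = 13)
  sss <- sss_estimate(pt, fx$attenuation, g, slice_stride = 1L,
                      axial_acceptance = 1)
  tr <- simulate_trues(pt, fx$attenuation, g)
  sf_sss <- sum(sss$values) / (sum(sss$values) + sum(tr$values))
  expect_equal(sf_sss, scatter_fraction(mc$tallies), tolerance = 0.15)
})

test_that("single-scatter estimate is linear and vanishes without inputs", {
  g <- default_geometry()
  fx <- disk_volumes()
  zero <- fx$activity; zero$values[] <- 0
  expect_true(all(sss_estimate(zero, fx$attenuation, g,
                               slice_stride = 1L)$values == 0))
  air <- fx$attenuation; air$values[] <- 0
  expect_warning(s0 <- sss_estimate(fx$activity, air, g, slice_stride = 1L),
                 "no attenuating medium")
  expect_true(all(s0$values == 0))
  s1 <- sss_estimate(fx$activity, fx$attenuation, g, slice_stride = 1L)
  a3 <- fx$activity; a3$values <- 3 * a3$values
  s3 <- sss_estimate(a3, fx$attenuation, g, slice_stride = 1L)
  expect_equal(s3$values, 3 * s1$values, tolerance = 1e-9)
})
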