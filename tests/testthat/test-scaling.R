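# tail mask construction, tail-fitted and Monte-Carlo scale factors

test_that("tail mask: all-air map is all tail; blobs above threshold shadow", {
  g <- default_geometry()
  fx <- disk_volumes(mu = 0.096)
  air <- fx$attenuation; air$values[] <- 0
  tm <- tail_mask(air, g)
  expect_true(all(tm$mask))
  tm2 <- tail_mask(fx$attenuation, g, dilate_bins = 0L)
  cbin <- which.min(abs(radial_centers(g)))
  expect_false(any(tm2$mask[cbin, , 1]))          # central LORs shadowed
  expect_true(all(tm2$mask[c(1, g$n_radial), , 1]))  # edge bins are tail
  # a sub-threshold blob outside the disk does not shadow
  sub <- fx$attenuation
  sub$values[130:133, 130:133, 1] <- 0.05
  tm3 <- tail_mask(sub, g, dilate_bins = 0L)
  expect_identical(tm3$mask, tm2$mask)
  # the same blob above threshold shrinks the tail
  sup <- fx$attenuation
  sup$values[130:133, 130:133, 1] <- 0.096
  tm4 <- tail_mask(sup, g, dilate_bins = 0L)
  expect_gt(sum(tm2$mask), sum(tm4$mask))
  expect_true(all(tm2$mask | !tm4$mask))
  expect_error(tail_mask(fx$attenuation, g, method = "nope"))
})

test_that("raising the image threshold never shrinks the tail", {
  g <- default_geometry()
  fx <- disk_volumes()
  masks <- lapply(c(0.05, 0.0935, 0.12), function(th)
    tail_mask(fx$attenuation, g, threshold = th)$mask)
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))
})

test_that("sinogram_acf mask variant thresholds the attenuation factors", {
  g <- default_geometry()
  fx <- disk_volumes()
  tm <- tail_mask(fx$attenuation, g, method = "sinogram_acf", dilate_bins = 0L)
  acf <- attenuation_factors(fx$attenuation, g)
  expect_identical(tm$mask, acf$values < 1.005)
})

test_that("tail fit recovers injected scale factors to 1e-6", {
  g <- default_geometry()
  fx <- disk_volumes()
  tm <- tail_mask(fx$attenuation, g)
  sss <- sss_estimate(fx$activity, fx$attenuation, g, slice_stride = 1L)
  tr <- simulate_trues(fx$activity, fx$attenuation, g)
  for (c0 in c(0.5, 1, 2, 4)) {
    em <- sinogram(tr$values + c0 * sss$values, g, "prompts")
    k <- tail_fit_scale(em, sss, tm)
    expect_equal(k, c0, tolerance = 1e-6)
  }
  # emission identical to sss on the tail: k = 1 exactly
  em1 <- sinogram(sss$values, g, "prompts")
  expect_equal(tail_fit_scale(em1, sss, tm), 1.0)
  # anti-correlated emission clips at zero
  emn <- sinogram(pmax(max(sss$values) - sss$values, 0), g, "prompts")
  expect_gte(tail_fit_scale(emn, sss, tm), 0)
  zs <- sinogram(array(0, dim(sss$values)), g, "scatter")
  expect_error(tail_fit_scale(em1, zs, tm), "no fittable tail")
  expect_equal(tail_fit_scale(em1, zs, tm, on_empty = "zero"), 0)
})

test_that("activity hidden in tail bins inflates the fitted scale", {
  g <- default_geometry()
  fx <- disk_volumes()
  tm <- tail_mask(fx$attenuation, g)
  sss <- sss_estimate(fx$activity, fx$attenuation, g, slice_stride = 1L)
  tr <- simulate_trues(fx$activity, fx$attenuation, g)
  clean <- sinogram(tr$values + sss$values, g, "prompts")
  k_clean <- tail_fit_scale(clean, sss, tm)
  # unmodelled hot source outside the mu-map's knowledge (mismatch)
  hot <- fx$activity; hot$values[] <- 0
  hot$values[72:73, 110:112, 1] <- 150
  contam <- sinogram(clean$values + forward_project(hot, g)$values, g, "prompts")
  k_bad <- tail_fit_scale(contam, sss, tm)
  expect_gt(k_bad, k_clean * 1.5)
})

test_that("Monte-Carlo scaling matches totals without any mask", {
  g <- scan_geometry(fov = 32, n_radial = 8, n_angles = 4)
  sss <- sinogram(array(200 / 32, c(8, 4, 1)), g, "scatter")
  em <- sinogram(array(1000 / 32, c(8, 4, 1)), g, "prompts")
  expect_equal(mc_scale(sss, em, 0.3), 1.5)
  expect_equal(mc_scale(sss, em, 0), 0)
  k <- mc_scale(sss, em, 0.3)
  expect_equal(sum(k * sss$values), 0.3 * sum(em$values), tolerance = 1e-9)
  zs <- sinogram(array(0, c(8, 4, 1)), g, "scatter")
  expect_error(mc_scale(zs, em, 0.3), "zero sss")
  expect_error(mc_scale(sss, em, 1.0), "in \\[0, 1\\)")
})

test_that("scatter estimates assemble per method", {
  g <- scan_geometry(fov = 32, n_radial = 8, n_angles = 4)
  nsc <- build_scatter_estimate("NSC", geometry = g, n_slices = 2)
  expect_true(all(nsc$sinogram$values == 0))
  expect_true(all(nsc$scale_k == 0))
  sss <- sinogram(array(runif(8 * 4 * 2), c(8, 4, 2)), g, "scatter")
  em <- sinogram(array(5, c(8, 4, 2)), g, "prompts")
  mcs <- build_scatter_estimate("MCS", sss = sss, emission = em, sf = 0.4)
  for (j in 1:2)
    expect_lte(sum(mcs$sinogram$values[, , j]), sum(em$values[, , j]))
  expect_error(build_scatter_estimate("TFS", sss = sss, emission = em),
               "tail mask")
})
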