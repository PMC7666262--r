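# halo detection, per-slice SUV, sinogram profiles

suv_cube <- function(vals) {
  voxel_volume(vals, c(4, 4, 4), quantity = "suv")
}

test_that("identical positive images contain no halo", {
  a <- array(1, c(12, 12, 6))
  h <- detect_halo(suv_cube(a), suv_cube(a))
  expect_equal(nrow(h), 0L)
})

test_that("a run of zeros inside a positive NSC body is one region", {
  sc <- array(1, c(12, 12, 6)); nsc <- array(1, c(12, 12, 6))
  sc[4:8, 6, 3] <- 0           # 5-voxel axis-aligned run
  h <- detect_halo(suv_cube(sc), suv_cube(nsc))
  expect_equal(nrow(h), 1L)
  expect_equal(h$size, 5L)
  expect_equal(c(h$slice_min, h$slice_max), c(3L, 3L))
  # too short a run is ignored
  sc2 <- array(1, c(12, 12, 6)); sc2[4:5, 6, 3] <- 0
  expect_equal(nrow(detect_halo(suv_cube(sc2), suv_cube(nsc))), 0L)
  # cold in NSC as well: genuinely cold tissue, not an artifact
  nsc2 <- nsc; nsc2[4:8, 6, 3] <- 0.05
  expect_equal(nrow(detect_halo(suv_cube(sc), suv_cube(nsc2))), 0L)
  # restricting the search region excludes the run
  roi <- array(TRUE, c(12, 12, 6)); roi[, 6, ] <- FALSE
  expect_equal(nrow(detect_halo(suv_cube(sc), suv_cube(nsc), roi = roi)), 0L)
  expect_error(detect_halo(suv_cube(sc),
                           voxel_volume(array(1, c(2, 2, 2)), 4,
                                        quantity = "suv")), "grids differ")
})

test_that("per-slice SUV means skip empty-mask slices", {
  img <- suv_cube(array(1, c(8, 8, 4)))
  mask <- array(TRUE, c(8, 8, 4))
  t1 <- suv_per_slice(img, mask)
  expect_equal(t1$mean_suv, rep(1, 4))
  img0 <- suv_cube(array(0, c(8, 8, 4)))
  expect_equal(suv_per_slice(img0, mask)$mean_suv, rep(0, 4))
  mask[, , 2] <- FALSE
  t2 <- suv_per_slice(img, mask)
  expect_equal(t2$slice, c(1L, 3L, 4L))
})

test_that("sinogram profiles extract one view with the tail extent", {
  g <- scan_geometry(fov = 64, n_radial = 16, n_angles = 8)
  z <- sinogram(array(0, c(16, 8, 2)), g, "scatter")
  e <- sinogram(array(seq_len(16 * 8 * 2) * 1.0, c(16, 8, 2)), g, "prompts")
  p <- sinogram_profiles(list(emission = e, scatter = z), slice = 2, angle = 3)
  expect_equal(nrow(p), 16L)
  expect_true(all(p$scatter == 0))
  expect_equal(p$emission, e$values[, 3, 2])
  expect_error(sinogram_profiles(list(e = e), slice = 9, angle = 1),
               "out of range")
})

test_that("circle fit recovers radius from noisy arc points", {
  set.seed(2)
  th <- seq(-pi / 2, pi / 2, length.out = 40)
  u <- 150 + 100 * cos(th) + rnorm(40, 0, 0.3)
  v <- 120 + 100 * sin(th) + rnorm(40, 0, 0.3)
  f <- fit_circle(u, v)
  expect_equal(f$radius, 100, tolerance = 0.01)
  expect_equal(f$center, c(150, 120), tolerance = 0.02)
})
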