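#' Smooth a sinogram in (radial, angle)
#'
#' Separable Gaussian in the radial and angular directions of every slice,
#' zero-padded at the array edges. Used to regularize Monte-Carlo scatter and
#' the single-scatter estimate.
#'
#' @param sino a `sinogram`.
#' @param fwhm_bins FWHM in bins, length 1 or 2 (radial, angle).
#' @return smoothed `sinogram`.
#' @export
smooth_sinogram <- function(sino, fwhm_bins = c(3, 3)) {
  if (length(fwhm_bins) == 1L) fwhm_bins <- rep(fwhm_bins, 2L)
  v <- sino$values
  d <- dim(v)
  kr <- gaussian_kernel_1d(fwhm_bins[1], 1)
  ka <- gaussian_kernel_1d(fwhm_bins[2], 1)
  dim(v) <- c(d[1], d[2] * d[3])
  v <- convolve_lines(v, kr)
  dim(v) <- d
  v <- aperm(v, c(2, 1, 3))
  dim(v) <- c(d[2], d[1] * d[3])
  v <- convolve_lines(v, ka)
  dim(v) <- c(d[2], d[1], d[3])
  v <- aperm(v, c(2, 1, 3))
  v[v < 0] <- 0
  sinogram(v, sino$geometry, sino$content)
}

dilate_radial <- function(mask, bins) {
  if (bins < 1L) return(mask)
  out <- mask
  n <- dim(mask)[1]
  for (s in seq_len(bins)) {
    out[seq_len(n - s), , ] <- out[seq_len(n - s), , ] | mask[(s + 1):n, , ]
    out[(s + 1):n, , ] <- out[(s + 1):n, , ] | mask[seq_len(n - s), , ]
  }
  out
}

#' Tail mask from a prepared mu-map
#'
#' Classifies sinogram bins as "tail" (assumed to contain only scattered
#' counts) from the reconstruction mu-map. Two methods:
#'
#' * `"image_mu"` (default): a bin is tail iff its line of response has zero
#'   path length through voxels with `mu >= threshold`. The default threshold
#'   (0.0935 1/cm) sits just below the attenuation of water/urine, mirroring
#'   the clinical tail threshold that sits a few percent below the catheter's
#'   attenuation: a coarse-voxel map keeps a catheter visible only where a
#'   voxel remains entirely inside the tube, which a grid-aligned straight
#'   catheter always has and an obliquely curving one mostly has not. The
#'   supra-threshold object shadow is dilated by `dilate_bins` radial bins
#'   before complementing, keeping the tail strictly outside the object.
#' * `"sinogram_acf"`: a bin is tail iff its attenuation correction factor is
#'   below `threshold` (default 1.005).
#'
#' A mu-map with finer axial sampling than the slice thickness contributes the
#' union of its sub-slice shadows (material anywhere within the axial slab
#' shadows the LOR).
#'
#' @param mumap prepared attenuation `voxel_volume` on the FOV grid.
#' @param geometry a `scan_geometry`.
#' @param method `"image_mu"` or `"sinogram_acf"`.
#' @param threshold 1/cm for `image_mu`; dimensionless ACF for `sinogram_acf`.
#' @param dilate_bins radial dilation of the object shadow (image_mu method).
#' @return object of class `tail_mask`: logical array `[radial, angle, slice]`.
#' @export
tail_mask <- function(mumap, geometry,
                      method = c("image_mu", "sinogram_acf"),
                      threshold = NULL, dilate_bins = 2L) {
  method <- match.arg(method)
  fz <- geometry$slice_thickness / mumap$voxel_size[3]
  if (abs(fz - round(fz)) > 1e-6 || fz < 1)
    stop("mu-map axial sampling must subdivide the slice thickness")
  fz <- as.integer(round(fz))
  if (method == "image_mu") {
    if (is.null(threshold)) threshold <- 0.0935
    bin <- mumap
    bin$values <- (mumap$values >= threshold) * 1
    proj <- forward_project(bin, geometry, "mask")
    hit <- proj$values > 0.5 * mumap$voxel_size[1]  # > half-voxel path
  } else {
    if (is.null(threshold)) threshold <- 1.005
    acf <- attenuation_factors(mumap, geometry)
    hit <- acf$values >= threshold
  }
  if (fz > 1L) {
    d <- dim(hit)
    ns <- d[3] %/% fz
    hit <- array(hit, c(d[1], d[2], fz, ns))
    hit <- apply(hit, c(1, 2, 4), any)
  }
  shadow <- dilate_radial(hit, as.integer(dilate_bins))
  structure(list(mask = !shadow, method = method, threshold = threshold,
                 dilate_bins = as.integer(dilate_bins)),
            class = "tail_mask")
}

#' @exportS3Method base::print
print.tail_mask <- function(x, ...) {
  cat(sprintf("<tail_mask> method %s, threshold %g, %.1f%% of bins are tail\n",
              x$method, x$threshold, 100 * mean(x$mask)))
  invisible(x)
}

#' Tail-fitted scale factor (TF-SSS)
#'
#' Per-slice non-negative least-squares scale: `k` minimizes
#' `sum_tail (emission - k * sss)^2`, closed form
#' `k = sum(emission * sss) / sum(sss^2)` over tail bins with `sss > 0`,
#' clipped at zero. This is where the halo mechanism lives: unmodelled
#' activity inside tail bins inflates `k`.
#'
#' @param emission random-corrected prompts `sinogram`.
#' @param sss unscaled single-scatter `sinogram`.
#' @param mask a [tail_mask].
#' @param on_empty `"error"` (default) to fail on an unfittable slice
#'   (no tail bins with positive sss), or `"zero"` to return 0 for it.
#' @return numeric vector, one fitted scale per slice.
#' @export
tail_fit_scale <- function(emission, sss, mask, on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  if (!identical(dim(emission$values), dim(sss$values)))
    stop("emission and sss must share dimensions")
  ns <- n_slices(emission)
  k <- numeric(ns)
  for (j in seq_len(ns)) {
    use <- mask$mask[, , j] & sss$values[, , j] > 0
    if (!any(use)) {
      if (on_empty == "error") stop(sprintf("slice %d has no fittable tail", j))
      k[j] <- 0
      next
    }
    e <- emission$values[, , j][use]
    s <- sss$values[, , j][use]
    k[j] <- max(0, sum(e * s) / sum(s * s))
  }
  k
}

#' Monte-Carlo scale factor (MC-SSS)
#'
#' Scales the single-scatter estimate so that, per slice, the scaled scatter
#' total is the Monte-Carlo scatter fraction of the emission total:
#' `k = sf * sum(emission) / sum(sss)`. No tail mask is involved, which is why
#' this scaling is immune to mu-map/activity mismatch.
#'
#' @param sss unscaled single-scatter `sinogram`.
#' @param emission random-corrected prompts `sinogram`.
#' @param sf scatter fraction in `[0, 1)`; scalar or one value per slice.
#' @return numeric vector, one scale per slice.
#' @export
mc_scale <- function(sss, emission, sf) {
  ns <- n_slices(emission)
  if (length(sf) == 1L) sf <- rep(sf, ns)
  if (length(sf) != ns) stop("sf must be scalar or one value per slice")
  if (any(sf < 0 | sf >= 1)) stop("sf must be in [0, 1)")
  k <- numeric(ns)
  for (j in seq_len(ns)) {
    tot_s <- sum(sss$values[, , j])
    tot_e <- sum(emission$values[, , j])
    if (tot_s == 0) {
      if (sf[j] > 0 && tot_e > 0)
        stop(sprintf("slice %d: zero sss total with positive scatter fraction", j))
      k[j] <- 0
    } else {
      k[j] <- sf[j] * tot_e / tot_s
    }
  }
  k
}

#' Assemble a scatter estimate for reconstruction
#'
#' * `"NSC"` — no scatter correction: a zero sinogram with scale 0.
#' * `"TFS"` — tail-fitted SSS: per-slice scale from [tail_fit_scale].
#' * `"MCS"` — Monte-Carlo-scaled SSS: per-slice scale from [mc_scale].
#'
#' @param method `"NSC"`, `"TFS"`, or `"MCS"`.
#' @param geometry a `scan_geometry` (required for NSC).
#' @param n_slices number of slices (required for NSC).
#' @param sss unscaled single-scatter `sinogram` (TFS, MCS).
#' @param emission random-corrected prompts `sinogram` (TFS, MCS).
#' @param mask a [tail_mask] (TFS).
#' @param sf scatter fraction, scalar or per slice (MCS).
#' @param mumap_voxel mu-map voxel size tag (mm), for bookkeeping.
#' @param on_empty passed to [tail_fit_scale].
#' @return object of class `scatter_estimate`: the scaled scatter sinogram,
#'   per-slice `scale_k`, the method tag and the mu-map voxel size.
#' @export
build_scatter_estimate <- function(method = c("NSC", "TFS", "MCS"),
                                   geometry = NULL, n_slices = NULL,
                                   sss = NULL, emission = NULL, mask = NULL,
                                   sf = NULL, mumap_voxel = NA_real_,
                                   on_empty = "error") {
  method <- match.arg(method)
  if (method == "NSC") {
    if (is.null(geometry)) geometry <- sss$geometry
    if (is.null(n_slices)) n_slices <- dim(sss$values)[3]
    v <- array(0, c(geometry$n_radial, geometry$n_angles, n_slices))
    return(structure(list(sinogram = sinogram(v, geometry, "scatter"),
                          scale_k = rep(0, n_slices), method = "NSC",
                          mumap_voxel = mumap_voxel),
                     class = "scatter_estimate"))
  }
  if (is.null(sss) || is.null(emission)) stop("sss and emission are required")
  k <- if (method == "TFS") {
    if (is.null(mask)) stop("TFS requires a tail mask")
    tail_fit_scale(emission, sss, mask, on_empty = on_empty)
  } else {
    if (is.null(sf)) stop("MCS requires a scatter fraction")
    mc_scale(sss, emission, sf)
  }
  v <- sss$values * rep(k, each = prod(dim(sss$values)[1:2]))
  structure(list(sinogram = sinogram(v, sss$geometry, "scatter"),
                 scale_k = k, method = method, mumap_voxel = mumap_voxel),
            class = "scatter_estimate")
}

#' @exportS3Method base::print
print.scatter_estimate <- function(x, ...) {
  cat(sprintf("<scatter_estimate> %s (mu-map %s mm), median scale %.3g\n",
              x$method, format(x$mumap_voxel), stats::median(x$scale_k)))
  invisible(x)
}
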