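#' Voxel volumes
#'
#' A `voxel_volume` is the common currency of the simulator: a 3-D scalar grid
#' holding either an activity concentration (kBq/mL), a linear attenuation
#' coefficient at 511 keV (1/cm), a standardized uptake value (dimensionless),
#' or integer region labels. The grid is described by a per-axis voxel size in
#' mm and the position (mm, scanner coordinates) of the centre of voxel
#' `[1, 1, 1]`.
#'
#' @param values numeric (or integer, for labels) 3-D array.
#' @param voxel_size numeric length-3, mm per axis; all strictly positive.
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param quantity one of `"activity"`, `"attenuation"`, `"suv"`, `"label"`.
#'
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, voxel_size, origin = c(0, 0, 0),
                         quantity = c("activity", "attenuation", "suv", "label")) {
  quantity <- match.arg(quantity)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite")
  if (quantity %in% c("activity", "attenuation", "suv") && any(values < 0))
    stop(sprintf("%s values must be non-negative", quantity))
  structure(
    list(values = values, voxel_size = voxel_size, origin = origin,
         quantity = quantity),
    class = "voxel_volume"
  )
}

#' @exportS3Method base::print
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %s, %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$quantity, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (mm): %.1f, %.1f, %.1f;  range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-centre coordinates along one axis
#' @param vol a `voxel_volume`.
#' @param axis integer 1..3.
#' @return numeric vector of mm coordinates.
#' @export
voxel_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$voxel_size[axis]
}

#' Block-average resampling
#'
#' Downsamples a volume by integer factors per axis, averaging each block of
#' `factors[1] x factors[2] x factors[3]` voxels. The grid is zero-padded at
#' the high end if a dimension is not divisible by its factor (padding with
#' zero preserves totals, not local means, in the padded fringe). The mean over
#' the represented physical extent is preserved exactly on divisible grids.
#'
#' @param vol a `voxel_volume`.
#' @param factors integer length-3 downsampling factors.
#' @return a `voxel_volume` on the coarser grid.
#' @export
block_average <- function(vol, factors) {
  factors <- as.integer(round(factors))
  if (length(factors) == 1L) factors <- rep(factors, 3L)
  if (any(factors < 1L)) stop("factors must be >= 1")
  v <- vol$values
  d <- dim(v)
  dpad <- as.integer(ceiling(d / factors) * factors)
  if (any(dpad != d)) {
    vp <- array(0, dpad)
    vp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v
    v <- vp
  }
  dn <- dpad %/% factors
  # sum within blocks axis by axis via dimension folding
  dim(v) <- c(factors[1], dn[1], dpad[2], dpad[3])
  v <- colSums(v)                                   # dn1 x d2p x d3p
  v <- aperm(v, c(2, 1, 3))
  dim(v) <- c(factors[2], dn[2], dn[1], dpad[3])
  v <- colSums(v)                                   # dn2 x dn1 x d3p
  v <- aperm(v, c(3, 1, 2))
  dim(v) <- c(factors[3], dn[3], dn[2], dn[1])
  v <- colSums(v)                                   # dn3 x dn2 x dn1
  v <- aperm(v, c(3, 2, 1)) / prod(factors)
  new_origin <- vol$origin + (factors - 1) / 2 * vol$voxel_size
  voxel_volume(v, vol$voxel_size * factors, new_origin, vol$quantity)
}

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(1)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k / sum(k)
}

# zero-padded 1-D convolution along the first dimension of a matrix whose
# columns are independent lines
convolve_lines <- function(m, kernel) {
  if (length(kernel) == 1L) return(m)
  half <- (length(kernel) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    shift <- j - 1L - half
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], ]
  }
  out
}

#' Separable 3-D Gaussian smoothing
#'
#' Isotropic (in mm) Gaussian filter applied separably along all three axes
#' with zero-value boundary handling; linear in the input. Mass within the
#' array is preserved up to leakage across the array boundary, so volumes must
#' carry a zero margin wider than ~3 sigma around any structure.
#'
#' @param vol a `voxel_volume`.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param axes axes to smooth along (default all three).
#' @return smoothed `voxel_volume`.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, axes = 1:3) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  v <- vol$values
  d <- dim(v)
  for (ax in axes) {
    k <- gaussian_kernel_1d(fwhm_mm, vol$voxel_size[ax])
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    inv <- order(perm)
    w <- aperm(v, perm)
    dw <- dim(w)
    dim(w) <- c(dw[1], dw[2] * dw[3])
    w <- convolve_lines(w, k)
    dim(w) <- dw
    v <- aperm(w, inv)
  }
  voxel_volume(pmax(v, 0), vol$voxel_size, vol$origin, vol$quantity)
}

#' Embed a volume into a larger zero grid
#'
#' Places `vol` onto a target grid (same voxel size) defined by `dim` and
#' `origin`, by nearest-voxel alignment; used to pad tight phantom boxes out to
#' the full field of view before projection.
#'
#' @param vol a `voxel_volume`.
#' @param dim integer length-3 target dimensions.
#' @param origin numeric length-3 target origin (mm).
#' @return a `voxel_volume` on the target grid.
#' @export
embed_volume <- function(vol, dim, origin) {
  if (max(abs((vol$origin - origin) / vol$voxel_size -
              round((vol$origin - origin) / vol$voxel_size))) > 1e-6)
    stop("source grid is not aligned with the target grid")
  off <- as.integer(round((vol$origin - origin) / vol$voxel_size))
  d <- base::dim(vol$values)
  out <- array(0, dim)
  src_lo <- pmax(1L, 1L - off)
  src_hi <- pmin(d, dim - off)
  if (any(src_hi < src_lo)) stop("volume lies outside the target grid")
  tgt_lo <- src_lo + off
  tgt_hi <- src_hi + off
  out[tgt_lo[1]:tgt_hi[1], tgt_lo[2]:tgt_hi[2], tgt_lo[3]:tgt_hi[3]] <-
    vol$values[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  voxel_volume(out, vol$voxel_size, origin, vol$quantity)
}
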