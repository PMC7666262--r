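#' Scanner geometry
#'
#' Defines the 2.5-D acquisition model: each 4-mm axial slice is an
#' independent 2-D parallel-beam problem with `n_angles` projection angles
#' uniformly covering \[0, pi) and `n_radial` radial bins of width
#' `fov / n_radial` centred on the scanner axis. The energy window and energy
#' resolution govern which scattered photons are accepted.
#'
#' @param fov transaxial field of view, mm.
#' @param n_radial number of radial bins.
#' @param n_angles number of projection angles.
#' @param slice_thickness axial slice thickness, mm.
#' @param energy_window keV pair accepted by the detector.
#' @param energy_resolution_fwhm fractional FWHM energy resolution at 511 keV.
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(fov = 576, n_radial = 144L, n_angles = 132L,
                          slice_thickness = 4,
                          energy_window = c(460, 665),
                          energy_resolution_fwhm = 0.116) {
  n_radial <- as.integer(n_radial); n_angles <- as.integer(n_angles)
  if (fov <= 0 || n_radial < 1L || n_angles < 1L || slice_thickness <= 0)
    stop("invalid geometry")
  if (length(energy_window) != 2L || energy_window[1] >= energy_window[2])
    stop("energy_window must be an increasing keV pair")
  structure(list(
    fov = fov, n_radial = n_radial, n_angles = n_angles,
    slice_thickness = slice_thickness,
    energy_window = as.numeric(energy_window),
    energy_resolution_fwhm = energy_resolution_fwhm,
    radial_width = fov / n_radial,
    angles = (seq_len(n_angles) - 1) * pi / n_angles
  ), class = "scan_geometry")
}

#' @exportS3Method base::print
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> fov %g mm, %d radial x %d angles, %g mm slices, window %g-%g keV\n",
    x$fov, x$n_radial, x$n_angles, x$slice_thickness,
    x$energy_window[1], x$energy_window[2]))
  invisible(x)
}

#' Radial bin centres (mm)
#' @param geometry a `scan_geometry`.
#' @export
radial_centers <- function(geometry) {
  (seq_len(geometry$n_radial) - (geometry$n_radial + 1) / 2) * geometry$radial_width
}

.projector_cache <- new.env(parent = emptyenv())

# Joseph-style parallel-beam system matrix for an n x n image of voxel size
# `voxel` mm centred on the scanner axis. Rows are sinogram bins ordered
# radial-fastest; columns are voxels in column-major array order (x fastest).
# Entry (b, v): intersection length (mm) of ray b with the bilinear footprint
# of voxel v, computed by stepping one voxel along the dominant ray axis and
# linearly interpolating along the other.
joseph_matrix <- function(geometry, n, voxel) {
  key <- sprintf("%d_%g_%d_%d_%g", n, voxel, geometry$n_radial,
                 geometry$n_angles, geometry$fov)
  if (!is.null(.projector_cache[[key]])) return(.projector_cache[[key]])
  nr <- geometry$n_radial
  s <- radial_centers(geometry)
  centers <- (seq_len(n) - (n + 1) / 2) * voxel   # voxel centre coordinates
  trip_i <- vector("list", geometry$n_angles)
  trip_j <- vector("list", geometry$n_angles)
  trip_x <- vector("list", geometry$n_angles)
  for (a in seq_len(geometry$n_angles)) {
    phi <- geometry$angles[a]
    c_ <- cos(phi); s_ <- sin(phi)
    # ray: P(t) = (s*cos - t*sin, s*sin + t*cos)
    if (abs(s_) <= abs(c_)) {
      # dominant axis y: step over y-planes, interpolate in x
      # x(y) = (s - y*sin)/cos
      step_len <- voxel / abs(c_)
      y <- rep(centers, each = nr)          # n*nr: y plane per (bin, step)
      sb <- rep(s, times = n)
      x <- (sb - y * s_) / c_
      fx <- (x - centers[1]) / voxel + 1
      i0 <- floor(fx)
      w1 <- fx - i0
      ok0 <- i0 >= 1 & i0 <= n
      ok1 <- (i0 + 1) >= 1 & (i0 + 1) <= n
      yidx <- rep(seq_len(n), each = nr)
      bin <- rep(seq_len(nr), times = n) + (a - 1L) * nr
      colv0 <- i0 + (yidx - 1) * n
      colv1 <- i0 + 1 + (yidx - 1) * n
      trip_i[[a]] <- c(bin[ok0], bin[ok1])
      trip_j[[a]] <- c(colv0[ok0], colv1[ok1])
      trip_x[[a]] <- c(((1 - w1) * step_len)[ok0], (w1 * step_len)[ok1])
    } else {
      # dominant axis x: step over x-planes, interpolate in y
      # y(x) = (s - x*cos)/sin
      step_len <- voxel / abs(s_)
      x <- rep(centers, each = nr)
      sb <- rep(s, times = n)
      y <- (sb - x * c_) / s_
      fy <- (y - centers[1]) / voxel + 1
      j0 <- floor(fy)
      w1 <- fy - j0
      ok0 <- j0 >= 1 & j0 <= n
      ok1 <- (j0 + 1) >= 1 & (j0 + 1) <= n
      xidx <- rep(seq_len(n), each = nr)
      bin <- rep(seq_len(nr), times = n) + (a - 1L) * nr
      colv0 <- xidx + (j0 - 1) * n
      colv1 <- xidx + j0 * n
      trip_i[[a]] <- c(bin[ok0], bin[ok1])
      trip_j[[a]] <- c(colv0[ok0], colv1[ok1])
      trip_x[[a]] <- c(((1 - w1) * step_len)[ok0], (w1 * step_len)[ok1])
    }
  }
  A <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(nr * geometry$n_angles, n * n)
  )
  .projector_cache[[key]] <- A
  A
}

# angle-interleaved row indices for OSEM subsets
subset_rows <- function(geometry, n_subsets) {
  nr <- geometry$n_radial
  lapply(seq_len(n_subsets), function(k) {
    ang <- seq(k, geometry$n_angles, by = n_subsets)
    as.vector(outer(seq_len(nr), (ang - 1L) * nr, `+`))
  })
}
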