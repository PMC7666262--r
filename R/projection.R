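#' Sinograms
#'
#' Per-slice projection data: a 3-D array `[radial bin, angle, slice]` plus the
#' geometry it was measured under and a content tag. Counts-like contents must
#' be non-negative; attenuation correction factors (`acf`) must be >= 1.
#'
#' @param values numeric array `[n_radial, n_angles, n_slices]`.
#' @param geometry a `scan_geometry`.
#' @param content one of `"prompts"`, `"trues"`, `"randoms"`, `"scatter"`,
#'   `"acf"`, `"mu_line_integral"`, `"mask"`.
#' @return object of class `sinogram`.
#' @export
sinogram <- function(values, geometry,
                     content = c("prompts", "trues", "randoms", "scatter",
                                 "acf", "mu_line_integral", "mask")) {
  content <- match.arg(content)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("sinogram values must be a 3-D array")
  d <- dim(values)
  if (d[1] != geometry$n_radial || d[2] != geometry$n_angles)
    stop("sinogram dimensions do not match geometry")
  if (content != "mask" && (anyNA(values) || any(!is.finite(values))))
    stop("sinogram values must be finite")
  if (content %in% c("prompts", "trues", "randoms", "scatter") && any(values < 0))
    stop("counts-type sinogram must be non-negative")
  if (content == "acf" && any(values < 1 - 1e-9))
    stop("acf must be >= 1 everywhere")
  structure(list(values = values, geometry = geometry, content = content),
            class = "sinogram")
}

#' @exportS3Method base::print
print.sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sinogram> %s, %d radial x %d angles x %d slices, total %.4g\n",
              x$content, d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

n_slices <- function(sino) dim(sino$values)[3]

# check that a volume is a square in-plane grid spanning the FOV, centred
check_fov_grid <- function(volume, geometry) {
  d <- dim(volume$values)
  if (d[1] != d[2] || volume$voxel_size[1] != volume$voxel_size[2])
    stop("volume must have a square in-plane grid")
  if (abs(d[1] * volume$voxel_size[1] - geometry$fov) > 1e-6)
    stop("volume in-plane extent must equal the field of view")
  ctr <- volume$origin[1:2] + (d[1] - 1) / 2 * volume$voxel_size[1:2]
  if (max(abs(ctr)) > 1e-6)
    stop("volume must be centred on the scanner axis")
  invisible(TRUE)
}

#' Forward projection (line integrals)
#'
#' Computes per-slice parallel-beam line integrals of a volume with a
#' Joseph-style bilinear ray tracer. Linear in the input; the same projector
#' backs data generation, scatter simulation masks, and reconstruction.
#' Output units: input units times mm.
#'
#' @param volume a `voxel_volume` whose in-plane grid spans the field of view.
#' @param geometry a `scan_geometry`.
#' @param content content tag for the resulting sinogram.
#' @return a `sinogram` with one slice per axial plane of `volume`.
#' @export
forward_project <- function(volume, geometry, content = "trues") {
  check_fov_grid(volume, geometry)
  d <- dim(volume$values)
  A <- joseph_matrix(geometry, d[1], volume$voxel_size[1])
  X <- matrix(volume$values, d[1] * d[2], d[3])
  Y <- as.matrix(A %*% X)
  Y[Y < 0] <- 0
  sinogram(array(Y, c(geometry$n_radial, geometry$n_angles, d[3])),
           geometry, content)
}

#' Back projection (adjoint of [forward_project])
#'
#' @param sino a `sinogram` with additive (counts-like) content.
#' @param geometry a `scan_geometry` (must match the sinogram's).
#' @param n in-plane image dimension.
#' @param voxel in-plane voxel size, mm; `n * voxel` must equal the FOV.
#' @return a `voxel_volume` (tagged `"activity"`), the exact adjoint image.
#' @export
back_project <- function(sino, geometry, n = geometry$n_radial,
                         voxel = geometry$fov / n) {
  if (!identical(dim(sino$values)[1:2],
                 c(geometry$n_radial, geometry$n_angles)))
    stop("sinogram does not match geometry")
  A <- joseph_matrix(geometry, n, voxel)
  d <- dim(sino$values)
  Y <- matrix(sino$values, d[1] * d[2], d[3])
  X <- as.matrix(Matrix::crossprod(A, Y))
  X[X < 0] <- 0
  nz <- d[3]
  voxel_volume(array(X, c(n, n, nz)), c(voxel, voxel, geometry$slice_thickness),
               c(-(n - 1) / 2 * voxel, -(n - 1) / 2 * voxel, 0), "activity")
}

#' Attenuation correction factors
#'
#' Line-integrates an attenuation map (1/cm) and exponentiates:
#' `acf = exp(integral of mu)` per line of response, >= 1 everywhere. The raw
#' line-integral sinogram is attached as attribute `"mu_line_integral"`.
#'
#' @param mumap a `voxel_volume` with quantity `"attenuation"` (1/cm).
#' @param geometry a `scan_geometry`.
#' @return a `sinogram` with content `"acf"`.
#' @export
attenuation_factors <- function(mumap, geometry) {
  if (mumap$quantity != "attenuation") stop("mumap must be an attenuation volume")
  li <- forward_project(mumap, geometry, content = "mu_line_integral")
  li$values <- li$values / 10  # (1/cm * mm) -> dimensionless
  out <- sinogram(exp(li$values), geometry, "acf")
  attr(out, "mu_line_integral") <- li
  out
}

#' Noiseless expected true coincidences
#'
#' `trues = count_scale * forward_project(activity) / acf(attenuation_true)`,
#' the standard attenuated line-integral model. Attenuation always uses the
#' physically present material (see [mismatch_pair]), not the mu-map handed to
#' the corrections.
#'
#' @param activity activity `voxel_volume` (kBq/mL) on a FOV-spanning grid.
#' @param attenuation_true attenuation `voxel_volume` on the same grid.
#' @param geometry a `scan_geometry`.
#' @param count_scale counts per (kBq/mL * mm) of activity line integral.
#' @return a `sinogram` with content `"trues"`.
#' @export
simulate_trues <- function(activity, attenuation_true, geometry,
                           count_scale = 1) {
  if (!identical(dim(activity$values), dim(attenuation_true$values)))
    stop("activity and attenuation must share grids")
  p <- forward_project(activity, geometry, "trues")
  acf <- attenuation_factors(attenuation_true, geometry)
  p$values <- count_scale * p$values / acf$values
  p
}

#' Poisson resampling of a sinogram
#'
#' Independent Poisson draw per bin with the input as expectation;
#' reproducible for a fixed seed.
#'
#' @param sino a non-negative `sinogram`.
#' @param seed integer RNG seed.
#' @return a `sinogram` of counts.
#' @export
add_poisson <- function(sino, seed) {
  if (any(sino$values < 0)) stop("negative input bins")
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  v <- sino$values
  v[] <- stats::rpois(length(v), lambda = as.vector(v))
  sinogram(v, sino$geometry, sino$content)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
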