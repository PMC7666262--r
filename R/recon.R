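#' Reconstruction settings
#'
#' @param iterations full OSEM iterations (default 3).
#' @param subsets ordered subsets; must divide the number of angles
#'   (default 11, giving 12 views per subset at 132 angles).
#' @param image_voxel reconstructed in-plane voxel size, mm.
#' @param scatter_mode `"additive"` places the scatter estimate inside the
#'   forward model (the standard form); `"presubtract"` subtracts it from the
#'   prompts and clips at zero, mirroring the sinogram non-negativity
#'   description - both drive over-corrected regions to zero.
#' @return object of class `recon_settings`.
#' @export
recon_settings <- function(iterations = 3L, subsets = 11L, image_voxel = 4,
                           scatter_mode = c("additive", "presubtract")) {
  scatter_mode <- match.arg(scatter_mode)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (subsets < 1L) stop("subsets must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 image_voxel = image_voxel, scatter_mode = scatter_mode),
            class = "recon_settings")
}

#' Ordered-subset expectation maximization
#'
#' Standard multiplicative OSEM with attenuation in the system model and an
#' additive scatter term: expected data per bin is
#' `count_scale * (A x) / acf + s`. The image is initialized uniformly
#' positive inside the field of view; non-negativity is inherent in the
#' multiplicative update, so bins where the scatter estimate exceeds the
#' prompts drive the overlapping voxels toward zero - the halo mechanism.
#' Deterministic: no randomness is involved.
#'
#' @param prompts prompts `sinogram` (random-corrected).
#' @param acf attenuation-correction-factor `sinogram` (>= 1), from the
#'   reconstruction mu-map.
#' @param scatter_est a `scatter_estimate` (see [build_scatter_estimate]) or a
#'   scatter `sinogram`.
#' @param geometry a `scan_geometry`.
#' @param settings a [recon_settings].
#' @param count_scale counts per (kBq/mL * mm); with the value used for the
#'   trues, the image is calibrated in kBq/mL without any data-driven
#'   normalization.
#' @param track_likelihood record the Poisson log-likelihood after every full
#'   iteration (attribute `"loglik"` of the result).
#' @return activity `voxel_volume` (kBq/mL).
#' @export
osem <- function(prompts, acf, scatter_est, geometry,
                 settings = recon_settings(), count_scale = 1,
                 track_likelihood = FALSE) {
  s_sino <- if (inherits(scatter_est, "scatter_estimate"))
    scatter_est$sinogram else scatter_est
  if (!identical(dim(prompts$values), dim(acf$values)) ||
      !identical(dim(prompts$values), dim(s_sino$values)))
    stop("prompts, acf and scatter must share geometry")
  if (geometry$n_angles %% settings$subsets)
    stop("subsets must divide the number of angles")
  n <- as.integer(round(geometry$fov / settings$image_voxel))
  if (abs(n * settings$image_voxel - geometry$fov) > 1e-6)
    stop("image voxel must tile the field of view")
  v <- settings$image_voxel
  A <- joseph_matrix(geometry, n, v)
  subs <- subset_rows(geometry, settings$subsets)
  Asub <- lapply(subs, function(r) A[r, , drop = FALSE])
  cx <- (seq_len(n) - (n + 1) / 2) * v
  fovmask <- outer(cx, cx, function(x, y) x^2 + y^2 <= (geometry$fov / 2)^2)
  nz <- n_slices(prompts)
  out <- array(0, c(n, n, nz))
  eps <- 1e-12
  ll <- if (track_likelihood)
    matrix(0, settings$iterations, nz) else NULL
  warned <- FALSE
  for (j in seq_len(nz)) {
    p <- as.vector(prompts$values[, , j])
    s <- as.vector(s_sino$values[, , j])
    if (settings$scatter_mode == "presubtract") {
      p <- pmax(p - s, 0)
      s <- rep(0, length(s))
    }
    if (sum(p) <= 0 && sum(s) <= 0) {
      if (!warned) { warning("degenerate slice with zero counts: zero image")
        warned <- TRUE }
      next
    }
    cfac <- count_scale / as.vector(acf$values[, , j])
    x <- as.numeric(fovmask)
    sens <- lapply(seq_along(subs), function(k)
      as.numeric(Matrix::crossprod(Asub[[k]], cfac[subs[[k]]])))
    for (it in seq_len(settings$iterations)) {
      for (k in seq_along(subs)) {
        r <- subs[[k]]
        m <- cfac[r] * as.numeric(Asub[[k]] %*% x) + s[r]
        ratio <- p[r] / pmax(m, eps)
        upd <- as.numeric(Matrix::crossprod(Asub[[k]], cfac[r] * ratio))
        x <- x * upd / pmax(sens[[k]], eps)
        x[!fovmask] <- 0
      }
      if (track_likelihood) {
        m_all <- cfac * as.numeric(A %*% x) + s
        ll[it, j] <- sum(p * log(pmax(m_all, eps)) - m_all)
      }
    }
    out[, , j] <- x
  }
  res <- voxel_volume(out, c(v, v, geometry$slice_thickness),
                      c(cx[1], cx[1], geometry$slice_thickness / 2), "activity")
  if (track_likelihood) attr(res, "loglik") <- ll
  res
}

#' Calibrate a reconstruction to standardized uptake values
#'
#' `SUV = concentration / calibration_reference`. The reconstruction is
#' already in concentration units because [osem] carries the analytically
#' known `count_scale` inside its forward model, so no data-driven
#' normalization is involved (the body concentration that defines SUV 1.0 is
#' the reference, 3.0 kBq/mL by default).
#'
#' @param image activity `voxel_volume` from [osem] (kBq/mL).
#' @param calibration_reference concentration defined as SUV 1.0, kBq/mL.
#' @return a `voxel_volume` with quantity `"suv"`.
#' @export
calibrate_suv <- function(image, calibration_reference = 3.0) {
  if (calibration_reference <= 0)
    stop("calibration_reference must be positive")
  voxel_volume(image$values / calibration_reference, image$voxel_size,
               image$origin, "suv")
}
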