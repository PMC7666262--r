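#' Run configuration
#'
#' One flat, serializable object holds everything a full experiment needs:
#' phantom layout, scanner geometry, scatter-simulation options, scaling
#' options, reconstruction settings, and the master seed. A run is
#' reproducible from its configuration alone.
#'
#' @param pattern phantom pattern (see [phantom_spec]).
#' @param methods correction methods to run, subset of
#'   `c("NSC", "TFS4", "TFS2", "MCS4")`.
#' @param seed master seed; per-stage seeds derive from it (see
#'   [derive_seed]).
#' @param phantom named list of [phantom_spec] overrides.
#' @param fov,n_radial,n_angles,slice_thickness,energy_window,
#'   energy_resolution_fwhm scanner geometry (see [scan_geometry]).
#' @param iterations,subsets,image_voxel,scatter_mode reconstruction settings
#'   (see [recon_settings]).
#' @param count_scale counts per (kBq/mL * mm) of the simulated trues.
#' @param n_decays Monte-Carlo decays for the ground-truth scatter.
#' @param max_scatter_order highest Compton order in the transport.
#' @param scatter_axial_acceptance probability that a scattered photon stays
#'   within the slice's axial acceptance (see [mc_transport]); applied
#'   consistently in the transport and the single-scatter simulation.
#' @param mc_smooth_bins (radial, angle) FWHM for smoothing the Monte-Carlo
#'   scatter before it enters the prompts.
#' @param sss_grid_spacing,sss_n_directions,sss_stride,sss_smooth_bins
#'   single-scatter-simulation resolution controls (see [sss_estimate]).
#' @param mumap_fwhm in-plane Gaussian FWHM (mm) of the mu-map preparation.
#' @param mask_method,mask_threshold,mask_dilate_bins tail-mask controls (see
#'   [tail_mask]).
#' @param sf_source `"truth"` uses the data-generation Monte-Carlo tallies for
#'   the MCS scatter fraction; `"mumap_estimate"` reruns a small transport on
#'   the reconstruction-side estimates (mu-map + NSC image).
#' @param sf_estimate_decays decays for the `"mumap_estimate"` rerun.
#' @param poisson add Poisson noise to the prompts (off by default: the study
#'   conditions use noiseless expected data so results are seed-stable).
#' @param calibration_reference concentration defining SUV 1.0, kBq/mL.
#' @param zero_epsilon,min_run,nsc_floor halo-detection controls (see
#'   [detect_halo]).
#' @return object of class `run_config`.
#' @export
run_config <- function(pattern = "tube_curve",
                       methods = c("NSC", "TFS4", "TFS2", "MCS4"),
                       seed = 1L,
                       phantom = list(),
                       fov = 576, n_radial = 144L, n_angles = 132L,
                       slice_thickness = 4,
                       energy_window = c(460, 665),
                       energy_resolution_fwhm = 0.116,
                       iterations = 3L, subsets = 11L, image_voxel = 4,
                       scatter_mode = "additive",
                       count_scale = 1,
                       n_decays = 2e6, max_scatter_order = 2L,
                       scatter_axial_acceptance = 0.5,
                       mc_smooth_bins = c(3, 3),
                       sss_grid_spacing = 20, sss_n_directions = 66L,
                       sss_stride = 2L, sss_smooth_bins = c(2, 2),
                       mumap_fwhm = 3,
                       mask_method = "image_mu", mask_threshold = NULL,
                       mask_dilate_bins = 1L,
                       sf_source = "truth", sf_estimate_decays = 5e5,
                       poisson = FALSE,
                       calibration_reference = 3.0,
                       zero_epsilon = 0.01, min_run = 3L, nsc_floor = 0.1) {
  cfg <- as.list(environment())
  bad <- setdiff(cfg$methods, c("NSC", "TFS4", "TFS2", "MCS4"))
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  if (cfg$n_angles %% cfg$subsets)
    stop("subsets must divide n_angles")
  if (!cfg$sf_source %in% c("truth", "mumap_estimate"))
    stop("sf_source must be 'truth' or 'mumap_estimate'")
  if (!cfg$mask_method %in% c("image_mu", "sinogram_acf"))
    stop("unknown mask_method")
  if (cfg$n_decays < 1) stop("n_decays must be >= 1")
  do.call(phantom_spec, c(list(pattern = cfg$pattern), cfg$phantom))  # validate
  class(cfg) <- "run_config"
  cfg
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> pattern %s, methods %s, seed %d\n",
              x$pattern, paste(x$methods, collapse = "/"), x$seed))
  invisible(x)
}

#' Scanner geometry of a configuration
#' @param config a [run_config].
#' @export
config_geometry <- function(config) {
  scan_geometry(fov = config$fov, n_radial = config$n_radial,
                n_angles = config$n_angles,
                slice_thickness = config$slice_thickness,
                energy_window = config$energy_window,
                energy_resolution_fwhm = config$energy_resolution_fwhm)
}

#' Deterministic per-stage seeds
#'
#' Expands the master seed into independent per-stage seeds so stages can be
#' re-run in isolation; stays below 2^31.
#'
#' @param seed master seed.
#' @param stage one of `"phantom"`, `"mc"`, `"poisson"`, `"sf_estimate"`.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  off <- c(phantom = 101L, mc = 211L, poisson = 307L, sf_estimate = 401L)
  if (!stage %in% names(off)) stop("unknown stage")
  as.integer((as.numeric(seed) * 7919 + off[[stage]]) %% 2147483647)
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected with a field-level message; omitted keys take the
#' documented defaults; the result is fully validated. An empty file yields
#' the default configuration.
#'
#' @param path YAML file path.
#' @return a [run_config].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$phantom)) raw$phantom <- as.list(raw$phantom)
  do.call(run_config, raw)
}

#' Save a run configuration to YAML
#' @param config a [run_config].
#' @param path output path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a volume as NIfTI
#'
#' Voxel size and origin go into the sform affine; values are stored as
#' float32 (computation stays float64 in memory).
#'
#' @param vol a `voxel_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  nii <- RNifti::asNifti(vol$values)
  RNifti::pixdim(nii) <- vol$voxel_size
  aff <- diag(c(vol$voxel_size, 1))
  aff[1:3, 4] <- vol$origin
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(aff, code = 2L))
  RNifti::writeNifti(nii, path, datatype = "float")
  invisible(path)
}

#' Serialize a sinogram
#'
#' Sinograms ride the NIfTI container with axes (radial, angle, slice) and
#' pixel dimensions (radial bin width, degrees per angle, slice thickness).
#' `sinogram_to_csv` writes the long-format per-slice table used for profile
#' plots.
#'
#' @param sino a `sinogram`.
#' @param path output path.
#' @export
write_sinogram <- function(sino, path) {
  g <- sino$geometry
  vol <- voxel_volume(sino$values,
                      c(g$radial_width, 180 / g$n_angles, g$slice_thickness),
                      c(radial_centers(g)[1], 0, g$slice_thickness / 2),
                      "activity")
  write_volume(vol, path)
}

#' @rdname write_sinogram
#' @param geometry the `scan_geometry` the file was written under.
#' @param content content tag to assign.
#' @export
read_sinogram <- function(path, geometry, content = "prompts") {
  v <- read_volume(path)
  sinogram(v$values, geometry, content)
}

#' @rdname write_sinogram
#' @export
sinogram_to_csv <- function(sino, path) {
  g <- sino$geometry
  d <- dim(sino$values)
  df <- data.frame(
    slice = rep(seq_len(d[3]), each = d[1] * d[2]),
    angle_deg = rep(rep(g$angles * 180 / pi, each = d[1]), d[3]),
    s_mm = rep(radial_centers(g), d[2] * d[3]),
    value = as.vector(sino$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @param quantity quantity tag to assign (NIfTI does not carry it).
#' @return a `voxel_volume`.
#' @export
read_volume <- function(path, quantity = "activity") {
  nii <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           conditionMessage(e)))
  aff <- RNifti::xform(nii)
  vals <- as.array(nii)
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  voxel_volume(vals, voxel_size = abs(diag(aff)[1:3]), origin = aff[1:3, 4],
               quantity = quantity)
}
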