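#' Analytic single-scatter simulation (SSS)
#'
#' Estimates the single-scatter sinogram from an activity estimate and an
#' attenuation map, per slice. For every scatter point S on a coarse grid
#' (spacing `grid_spacing`, restricted to attenuating voxels) and every
#' discretized photon direction, the attenuated emission integral along the
#' ray from S is combined with the Klein-Nishina angular weight, the
#' energy-window acceptance of the downscattered photon, and the attenuation
#' of the scattered leg (with the attenuation coefficient scaled to the
#' scattered energy); the event is binned on the line of response joining the
#' two detector-ring intersections. Multiple scatter and out-of-slice scatter
#' are by construction absent - the estimate genuinely underestimates total
#' scatter and the scaling step (tail fit or Monte-Carlo fraction) has real
#' work to do.
#'
#' The output is normalized to the same units as [simulate_trues] at the same
#' `count_scale`, so scatter-to-trues ratios are directly comparable with the
#' Monte-Carlo transport's tallies.
#'
#' @param activity_est activity estimate `voxel_volume` on a FOV grid
#'   (typically the no-scatter-correction reconstruction).
#' @param mumap prepared attenuation `voxel_volume` on a FOV grid; finer axial
#'   sampling than the slice thickness is averaged per slice.
#' @param geometry a `scan_geometry`.
#' @param grid_spacing scatter-point grid spacing, mm (default 20).
#' @param count_scale counts per (kBq/mL * mm), must match the trues.
#' @param n_directions even number of discretized photon directions.
#' @param slice_stride compute every k-th slice and interpolate between
#'   (scatter varies slowly axially).
#' @param smoothing_fwhm_bins Gaussian smoothing of the result in
#'   (radial, angle) bins.
#' @param ray_step ray-integration step, mm.
#' @param theta_max_deg largest scattering angle carried (beyond ~55 degrees
#'   the energy window acceptance is negligible for 511 keV).
#' @param axial_acceptance probability that the scattered photon stays within
#'   the slice's axial acceptance; must match the Monte-Carlo transport's
#'   value (see [mc_transport]).
#' @param mu_min minimum attenuation (1/cm) for a voxel to scatter.
#' @return a `sinogram` with content `"scatter"`, unscaled.
#' @export
sss_estimate <- function(activity_est, mumap, geometry, grid_spacing = 20,
                         count_scale = 1, n_directions = 66L,
                         slice_stride = 2L, smoothing_fwhm_bins = c(2, 2),
                         ray_step = 4, theta_max_deg = 55,
                         axial_acceptance = 0.5, mu_min = 0.01) {
  check_fov_grid(activity_est, geometry)
  check_fov_grid(mumap, geometry)
  nz <- dim(activity_est$values)[3]
  # average mu-map sub-slices onto the data slices
  fz <- geometry$slice_thickness / mumap$voxel_size[3]
  if (abs(fz - round(fz)) > 1e-6 || round(fz) < 1)
    stop("mu-map axial sampling must subdivide the slice thickness")
  mu_v <- mumap$values
  if (round(fz) > 1) {
    d <- dim(mu_v)
    mu_v <- array(mu_v, c(d[1] * d[2], round(fz), d[3] / round(fz)))
    mu_v <- apply(mu_v, c(1, 3), mean)
    dim(mu_v) <- c(d[1], d[2], dim(mu_v)[2])
  }
  if (dim(mu_v)[3] != nz) stop("activity and mu-map slice counts differ")
  n_dir <- as.integer(n_directions)
  if (n_dir %% 2L) stop("n_directions must be even")
  nr <- geometry$n_radial; na <- geometry$n_angles
  r_det <- geometry$fov / sqrt(2)
  dirs <- (seq_len(n_dir) - 1) * 2 * pi / n_dir
  dtheta <- 2 * pi / n_dir
  m_max <- max(1L, floor(theta_max_deg * pi / 180 / dtheta))
  ms <- -m_max:m_max
  thetas <- ms * dtheta
  # in-plane Klein-Nishina density, normalized over the full circle; the
  # angular weight of each direction bin integrates density x window
  # acceptance over the bin (both vary steeply near forward scatter)
  th_fine <- seq(-pi, pi, length.out = 8001)
  kn_norm <- sum(kn_diff(th_fine)) * (th_fine[2] - th_fine[1])
  w_eff <- vapply(ms, function(m) {
    tt <- seq((m - 0.5) * dtheta, (m + 0.5) * dtheta, length.out = 51)
    ww <- kn_diff(tt) / kn_norm *
      window_acceptance(compton_energy(tt), geometry)
    sum(ww) * (tt[2] - tt[1])
  }, numeric(1))
  e_sc <- compton_energy(thetas)
  g_sc <- mu_energy_scale(e_sc)
  w511 <- window_acceptance(ELECTRON_REST, geometry)
  f_c <- compton_fraction(ELECTRON_REST)
  # scatter-point grid
  gs <- seq(-geometry$fov / 2 + grid_spacing / 2, geometry$fov / 2,
            by = grid_spacing)
  sxg <- rep(gs, times = length(gs)); syg <- rep(gs, each = length(gs))
  n_steps <- as.integer(ceiling(2 * r_det / ray_step))
  tmid <- (seq_len(n_steps) - 0.5) * ray_step
  va <- activity_est$voxel_size[1]; ax0 <- activity_est$origin[1]
  ay0 <- activity_est$origin[2]
  vm <- mumap$voxel_size[1]; mx0 <- mumap$origin[1]; my0 <- mumap$origin[2]
  out <- array(0, c(nr, na, nz))
  slices <- unique(c(seq(1L, nz, by = as.integer(slice_stride)), nz))
  warned <- FALSE
  # normalization to trues units: per-direction weight d_nu/(2pi) = 1/n_dir,
  # scatter-cell area, the sinogram's angle multiplicity / radial width, and
  # a factor 2 because either photon of the pair may be the scattered one
  kfac <- 2 * axial_acceptance * count_scale * na /
    (geometry$radial_width * w511) * grid_spacing^2 / n_dir
  for (j in slices) {
    mu2d <- mu_v[, , j]
    act2d <- activity_est$values[, , j]
    mu_s <- sample_bilinear(mu2d, sxg, syg, vm, mx0, my0)
    sel <- mu_s >= mu_min
    if (!any(sel)) {
      if (!warned && sum(act2d) > 0) {
        warning("no attenuating medium: zero scatter estimate")
        warned <- TRUE
      }
      next
    }
    sx <- sxg[sel]; sy <- syg[sel]; mus <- mu_s[sel]
    n_s <- length(sx)
    L <- matrix(0, n_s, n_dir)    # attenuation line integral S -> ring
    lam <- matrix(0, n_s, n_dir)  # emission integral along the ray
    axx <- matrix(0, n_s, n_dir)  # ring intersection
    ayy <- matrix(0, n_s, n_dir)
    for (l in seq_len(n_dir)) {
      uxl <- cos(dirs[l]); uyl <- sin(dirs[l])
      t_exit <- ray_exit_t(sx, sy, uxl, uyl, r_det)
      axx[, l] <- sx + t_exit * uxl
      ayy[, l] <- sy + t_exit * uyl
      pxs <- rep(sx, n_steps) + rep(tmid, each = n_s) * uxl
      pys <- rep(sy, n_steps) + rep(tmid, each = n_s) * uyl
      inside <- rep(tmid, each = n_s) <= rep(t_exit, n_steps)
      muv <- numeric(n_s * n_steps)
      acv <- numeric(n_s * n_steps)
      muv[inside] <- sample_bilinear(mu2d, pxs[inside], pys[inside], vm, mx0, my0)
      acv[inside] <- sample_bilinear(act2d, pxs[inside], pys[inside], va, ax0, ay0)
      dim(muv) <- c(n_s, n_steps); dim(acv) <- c(n_s, n_steps)
      L[, l] <- rowSums(muv) * ray_step / 10
      lam[, l] <- rowSums(acv) * ray_step
    }
    emis <- lam * exp(-L)  # attenuated emission reaching the ring unscattered
    acc_val <- numeric(0); acc_bin <- integer(0)
    half <- n_dir %/% 2L
    for (mi in seq_along(ms)) {
      l2 <- ((seq_len(n_dir) - 1L + half + ms[mi]) %% n_dir) + 1L
      C <- kfac * (mus / 10) * f_c * emis * w_eff[mi] *
        exp(-g_sc[mi] * L[, l2, drop = FALSE])
      bins <- lor_bins(axx, ayy, axx[, l2, drop = FALSE],
                       ayy[, l2, drop = FALSE], geometry)
      ok <- !is.na(bins) & C > 0
      acc_val <- c(acc_val, C[ok]); acc_bin <- c(acc_bin, bins[ok])
    }
    if (length(acc_bin)) {
      sl <- numeric(nr * na)
      agg <- rowsum(acc_val, acc_bin)
      sl[as.integer(rownames(agg))] <- agg
      out[, , j] <- sl
    }
  }
  # axial interpolation of skipped slices
  for (j in setdiff(seq_len(nz), slices)) {
    lo <- max(slices[slices < j]); hi <- min(slices[slices > j])
    w <- (j - lo) / (hi - lo)
    out[, , j] <- (1 - w) * out[, , lo] + w * out[, , hi]
  }
  smooth_sinogram(sinogram(out, geometry, "scatter"), smoothing_fwhm_bins)
}
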