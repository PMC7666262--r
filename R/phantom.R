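#' Phantom specification
#'
#' Describes the body-and-catheter phantom: a water-filled elliptical cylinder
#' standing in for a NEMA-style body phantom with the sphere inserts removed,
#' plus a 9-mm outer / 7-mm inner vinyl-chloride urinary catheter arranged in
#' one of the study layouts:
#'
#' * `"urine_shift"` — a straight axial catheter beside the body divided into
#'   four consecutive segments (default 4 cm each) realizing the
#'   CT+/PET+, CT-/PET+, CT+/PET-, CT-/PET- fill combinations, in that axial
#'   order; the CT-/PET+ segment carries activity the attenuation truth for CT
#'   does not know about.
#' * `"tube_curve"` — the catheter bent into a semicircular arc (default
#'   radius 10 cm) in the sagittal plane, its closest point a configurable gap
#'   (default 5 cm) from the body surface, filled with activity throughout.
#' * `"skin_attached"` — the mitigation layout: the catheter runs along the
#'   body surface (centreline on the skin) with the same fill as
#'   `"tube_curve"`.
#' * `"none"` — body only.
#'
#' @param pattern catheter layout, see above.
#' @param body_semi_axes body ellipse semi-axes, cm (x then y).
#' @param body_length axial body length, cm (rounded to whole 4-mm slices).
#' @param catheter_outer_diameter catheter outer diameter, mm.
#' @param catheter_wall_thickness wall thickness, mm.
#' @param segment_length urine-shift segment length, cm.
#' @param arc_radius tube-curve arc radius, cm.
#' @param arc_offset gap between body surface and the catheter, cm
#'   (also used for the straight urine-shift catheter).
#' @param activity_catheter lumen activity where urine is present, kBq/mL.
#' @param activity_body body activity, kBq/mL (3.0 = SUV 1.0 reference).
#' @param mu_water linear attenuation of water/urine at 511 keV, 1/cm.
#' @param mu_catheter_wall wall attenuation, 1/cm.
#' @param truth_voxel truth-grid voxel size, mm (in-plane, in-plane, axial).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(pattern = c("none", "urine_shift", "tube_curve",
                                     "skin_attached"),
                         body_semi_axes = c(15, 10), body_length = 24,
                         catheter_outer_diameter = 9,
                         catheter_wall_thickness = 1,
                         segment_length = 4, arc_radius = 10, arc_offset = 5,
                         activity_catheter = 150, activity_body = 3.0,
                         mu_water = 0.096, mu_catheter_wall = 0.103,
                         truth_voxel = c(1, 1, 1)) {
  pattern <- match.arg(pattern)
  inner <- catheter_outer_diameter - 2 * catheter_wall_thickness
  if (inner <= 0) stop("catheter inner diameter must be positive")
  if (activity_catheter < 0 || activity_body < 0) stop("activities must be >= 0")
  if (mu_water < 0 || mu_catheter_wall < 0) stop("attenuation must be >= 0")
  if (any(truth_voxel <= 0)) stop("truth_voxel must be positive")
  if (any(body_semi_axes <= 0) || body_length <= 0) stop("invalid body shape")
  structure(list(
    pattern = pattern,
    body_semi_axes = body_semi_axes, body_length = body_length,
    catheter_outer_diameter = catheter_outer_diameter,
    catheter_wall_thickness = catheter_wall_thickness,
    segment_length = segment_length, arc_radius = arc_radius,
    arc_offset = arc_offset,
    activity_catheter = activity_catheter, activity_body = activity_body,
    mu_water = mu_water, mu_catheter_wall = mu_catheter_wall,
    truth_voxel = as.numeric(truth_voxel)
  ), class = "phantom_spec")
}

# Region labels. Lumen labels encode the urine-shift fill combinations.
LBL_AIR <- 0L; LBL_BODY <- 1L; LBL_WALL <- 2L; LBL_LUMEN <- 3L
LBL_CTP_PETP <- 10L; LBL_CTM_PETP <- 11L; LBL_CTP_PETM <- 12L; LBL_CTM_PETM <- 13L

#' @export
label_table <- function() {
  data.frame(
    label = c(LBL_AIR, LBL_BODY, LBL_WALL, LBL_LUMEN, LBL_CTP_PETP,
              LBL_CTM_PETP, LBL_CTP_PETM, LBL_CTM_PETM),
    name = c("air", "body", "catheter_wall", "lumen", "lumen CT+/PET+",
             "lumen CT-/PET+", "lumen CT+/PET-", "lumen CT-/PET-"),
    stringsAsFactors = FALSE
  )
}

# snap a [lo, hi] mm interval (1-mm voxels) so that voxel centres sit at
# 0.5 mod 4 and the count is divisible by 4: then 2x and 4x block averages
# land exactly on the 2-mm and 4-mm full-FOV grid centres.
snap_extent_1mm <- function(lo, hi) {
  x0 <- 0.5 + 4 * floor((lo - 0.5) / 4)
  n <- 4L * as.integer(ceiling((hi - x0 + 1) / 4))
  list(origin = x0, n = n)
}

#' Generate a phantom truth
#'
#' Renders the paired ground-truth volumes on a fine grid (default 1-mm
#' in-plane, 2-mm axial, chosen so the 1-mm catheter wall is representable and
#' block averages align exactly with the 2-mm and 4-mm reconstruction grids):
#'
#' * `activity` — the emission distribution during PET (kBq/mL),
#' * `attenuation_ct` — what the CT saw (the mu-map source; in the urine-shift
#'   CT- segments the catheter is absent here),
#' * `attenuation_pet` — the material physically present during the PET
#'   acquisition (always includes whatever emits),
#' * `labels` — integer region ids (see [label_table]).
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed (kept for interface symmetry; the generator is
#'   deterministic).
#' @return object of class `phantom_truth`.
#' @export
make_phantom <- function(spec, seed = 0L) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  vx <- spec$truth_voxel
  a <- spec$body_semi_axes[1] * 10; b <- spec$body_semi_axes[2] * 10  # mm
  n_sl <- max(1L, as.integer(round(spec$body_length * 10 / 4)))
  len_z <- n_sl * 4
  r_out <- spec$catheter_outer_diameter / 2
  r_in <- r_out - spec$catheter_wall_thickness
  margin <- 14
  y_max_need <- b
  if (spec$pattern == "urine_shift")
    y_max_need <- b + spec$arc_offset * 10 + r_out
  if (spec$pattern == "tube_curve")
    y_max_need <- b + spec$arc_offset * 10 + spec$arc_radius * 10 + r_out
  if (spec$pattern == "skin_attached")
    y_max_need <- b + r_out
  if (abs(vx[1] - 1) < 1e-9 && abs(vx[2] - 1) < 1e-9) {
    sx <- snap_extent_1mm(-(a + margin), a + margin)
    sy <- snap_extent_1mm(-(b + margin), y_max_need + margin)
  } else {
    sx <- list(origin = -(a + margin), n = as.integer(ceiling(2 * (a + margin) / vx[1])))
    sy <- list(origin = -(b + margin), n = as.integer(ceiling((y_max_need + b + 2 * margin) / vx[2])))
  }
  nz <- as.integer(round(len_z / vx[3]))
  z0 <- vx[3] / 2
  xs <- sx$origin + (seq_len(sx$n) - 1) * vx[1]
  ys <- sy$origin + (seq_len(sy$n) - 1) * vx[2]
  zs <- z0 + (seq_len(nz) - 1) * vx[3]
  if (max(abs(c(sx$origin, xs[length(xs)], sy$origin, ys[length(ys)]))) + r_out > 288)
    stop("phantom extends beyond the field of view")

  body2d <- outer(xs / a, rep(1, sy$n))^2 + outer(rep(1, sx$n), ys / b)^2 <= 1
  body_act <- ifelse(body2d, spec$activity_body, 0)
  body_mu <- ifelse(body2d, spec$mu_water, 0)
  body_lab <- ifelse(body2d, LBL_BODY, LBL_AIR)

  act <- array(rep(body_act, nz), c(sx$n, sy$n, nz))
  mu_ct <- array(rep(body_mu, nz), c(sx$n, sy$n, nz))
  mu_pet <- mu_ct
  lab <- array(rep(as.integer(body_lab), nz), c(sx$n, sy$n, nz))

  # catheter in-plane bounding window (catheter lives near x = 0)
  ixw <- which(abs(xs) <= r_out + 2)
  y_cath <- switch(spec$pattern,
    urine_shift   = b + spec$arc_offset * 10 + r_out,
    skin_attached = b,
    NA_real_)
  R <- spec$arc_radius * 10
  y_arc0 <- b + spec$arc_offset * 10   # arc endpoints' y (closest approach)
  z_c <- len_z / 2
  iyw <- if (spec$pattern == "tube_curve") {
    which(ys >= y_arc0 - r_out - 2 & ys <= y_arc0 + R + r_out + 2)
  } else if (!is.na(y_cath)) {
    which(abs(ys - y_cath) <= r_out + 2)
  } else integer(0)
  if (length(iyw)) {
    XXw <- matrix(xs[ixw], length(ixw), length(iyw))
    YYw <- matrix(ys[iyw], length(ixw), length(iyw), byrow = TRUE)
    if (!is.na(y_cath)) d2d <- sqrt(XXw^2 + (YYw - y_cath)^2)
  }

  seg_len <- spec$segment_length * 10
  z_seg0 <- (len_z - 4 * seg_len) / 2  # catheter start (urine shift)
  if (spec$pattern == "urine_shift" && (z_seg0 < 0 || z_seg0 + 4 * seg_len > len_z))
    stop("urine-shift segments do not fit in the body length")

  if (spec$pattern != "none") for (k in seq_len(nz)) {
    z <- zs[k]
    if (spec$pattern %in% c("urine_shift", "skin_attached")) {
      if (spec$pattern == "urine_shift") {
        if (z < z_seg0 || z > z_seg0 + 4 * seg_len) next
        seg <- min(1L + as.integer(floor((z - z_seg0) / seg_len)), 4L)
        ct_has <- seg %in% c(1L, 3L)   # CT+/PET+, CT+/PET-
        pet_has <- seg %in% c(1L, 2L)  # CT+/PET+, CT-/PET+
        lumen_lab <- c(LBL_CTP_PETP, LBL_CTM_PETP, LBL_CTP_PETM, LBL_CTM_PETM)[seg]
      } else {
        if (abs(z - z_c) > R) next
        ct_has <- TRUE; pet_has <- TRUE; lumen_lab <- LBL_LUMEN
      }
      d <- d2d
    } else { # tube_curve: 3-D distance to the arc (sagittal plane x = 0)
      dz <- z - z_c
      if (abs(dz) > R + r_out) next
      rho <- sqrt((YYw - y_arc0)^2 + dz^2)
      d <- ifelse(YYw >= y_arc0,
                  sqrt(XXw^2 + (rho - R)^2),
                  pmin(sqrt(XXw^2 + (YYw - y_arc0)^2 + (dz - R)^2),
                       sqrt(XXw^2 + (YYw - y_arc0)^2 + (dz + R)^2)))
      ct_has <- TRUE; pet_has <- TRUE; lumen_lab <- LBL_LUMEN
    }
    wall <- d > r_in & d <= r_out
    lumen <- d <= r_in
    if (!any(lumen) && !any(wall)) next
    A <- act[ixw, iyw, k]; MC <- mu_ct[ixw, iyw, k]
    MP <- mu_pet[ixw, iyw, k]; L <- lab[ixw, iyw, k]
    # the tube displaces whatever it overlaps (body, for skin_attached)
    A[wall] <- 0; A[lumen] <- if (pet_has) spec$activity_catheter else 0
    MP[wall] <- spec$mu_catheter_wall
    MP[lumen] <- if (pet_has) spec$mu_water else 0
    if (ct_has) {
      MC[wall] <- spec$mu_catheter_wall
      MC[lumen] <- spec$mu_water
    } else {
      MC[wall] <- 0; MC[lumen] <- 0
    }
    L[wall] <- LBL_WALL; L[lumen] <- lumen_lab
    act[ixw, iyw, k] <- A; mu_ct[ixw, iyw, k] <- MC
    mu_pet[ixw, iyw, k] <- MP; lab[ixw, iyw, k] <- L
  }

  origin <- c(sx$origin, sy$origin, z0)
  structure(list(
    spec = spec,
    activity = voxel_volume(act, vx, origin, "activity"),
    attenuation_ct = voxel_volume(mu_ct, vx, origin, "attenuation"),
    attenuation_pet = voxel_volume(mu_pet, vx, origin, "attenuation"),
    labels = voxel_volume(lab, vx, origin, "label"),
    n_slices = n_sl
  ), class = "phantom_truth")
}

#' @exportS3Method base::print
print.phantom_truth <- function(x, ...) {
  grid <- if (!is.null(x$labels))
    paste(dim(x$labels$values), collapse = " x ") else "summary only"
  cat(sprintf("<phantom_truth> pattern %s, %d slices, grid %s\n",
              x$spec$pattern, x$n_slices, grid))
  invisible(x)
}

#' Skin-attached mitigation variant
#'
#' Convenience wrapper: renders the catheter in contact with the body surface
#' (centreline on the skin) so its projection shadow is contiguous with the
#' body's, with activity and attenuation fills identical to the tube-curve
#' defaults.
#'
#' @param spec a [phantom_spec]; its pattern is forced to `"skin_attached"`.
#' @return a `phantom_truth`.
#' @export
skin_attached_variant <- function(spec) {
  spec$pattern <- "skin_attached"
  make_phantom(spec)
}

#' Prepare a reconstruction mu-map
#'
#' The partial-volume pipeline that drives the artifact: block-average the
#' fine attenuation truth to the target isotropic voxel size (4 mm or 2 mm),
#' then smooth with an in-plane 2-D Gaussian (CT-derived attenuation maps are
#' processed slice by slice; the axial partial volume enters through the
#' block averaging of fine axial planes into the coarse voxel). Linear in the
#' input; the mean attenuation over the represented extent is preserved. With
#' `fov` given, the result is additionally zero-embedded in-plane onto the
#' full field-of-view reconstruction grid.
#'
#' @param attenuation_ct fine-grid attenuation `voxel_volume` (1/cm).
#' @param target_voxel isotropic target voxel size, mm; must be an integer
#'   multiple of every truth voxel dimension.
#' @param smoothing_fwhm Gaussian FWHM, mm (>= 0). The default (3 mm) is mild:
#'   the attenuation-map partial volume that hides the catheter comes chiefly
#'   from the voxel averaging, and a fully-interior catheter voxel must remain
#'   near the material's attenuation for the near-threshold tail mask to keep
#'   straight catheters visible (see [tail_mask]).
#' @param fov optional transaxial field of view (mm) to embed into.
#' @return attenuation `voxel_volume` at `target_voxel`.
#' @export
prepare_mumap <- function(attenuation_ct, target_voxel = 4, smoothing_fwhm = 3,
                          fov = NULL) {
  if (attenuation_ct$quantity != "attenuation")
    stop("input must be an attenuation volume")
  if (smoothing_fwhm < 0) stop("smoothing_fwhm must be >= 0")
  ext <- dim(attenuation_ct$values) * attenuation_ct$voxel_size
  if (target_voxel > min(ext))
    stop("target_voxel exceeds the volume extent")
  f <- target_voxel / attenuation_ct$voxel_size
  if (max(abs(f - round(f))) > 1e-9 || any(f < 1 - 1e-9))
    stop("target_voxel must be an integer multiple of the truth voxel size")
  out <- block_average(attenuation_ct, as.integer(round(f)))
  out <- gaussian_smooth(out, smoothing_fwhm, axes = 1:2)
  if (!is.null(fov)) {
    n <- as.integer(round(fov / target_voxel))
    out <- embed_volume(out, c(n, n, dim(out$values)[3]),
                        c(rep(-(n - 1) / 2 * target_voxel, 2), out$origin[3]))
  }
  out
}

#' Emission/attenuation volumes for simulation vs correction
#'
#' Splits a phantom truth into the volume pair each pipeline stage consumes:
#' the PET simulator gets the emission distribution and the attenuation of the
#' material physically present during PET (shifted urine attenuates its own
#' emission even though the CT never saw it); the mu-map pipeline gets the CT
#' attenuation truth.
#'
#' @param truth a `phantom_truth`.
#' @return list with `activity_for_pet`, `attenuation_for_pet`,
#'   `attenuation_for_ct`.
#' @export
mismatch_pair <- function(truth) {
  if (!inherits(truth, "phantom_truth")) stop("truth must be a phantom_truth")
  list(activity_for_pet = truth$activity,
       attenuation_for_pet = truth$attenuation_pet,
       attenuation_for_ct = truth$attenuation_ct)
}
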