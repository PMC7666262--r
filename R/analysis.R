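# ---- mask utilities on the reconstruction grid ----------------------------

# length of the maximal run of TRUE containing each voxel, along one axis
run_lengths_along <- function(mask, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  inv <- order(perm)
  m <- aperm(mask, perm)
  d <- dim(m)
  dim(m) <- c(d[1], d[2] * d[3])
  fwd <- matrix(0L, d[1], ncol(m))
  acc <- integer(ncol(m))
  for (i in seq_len(d[1])) {
    acc <- ifelse(m[i, ], acc + 1L, 0L)
    fwd[i, ] <- acc
  }
  run <- fwd
  acc <- fwd[d[1], ]
  for (i in rev(seq_len(d[1] - 1L))) {
    acc <- ifelse(m[i + 1L, ] & m[i, ], acc, fwd[i, ])
    run[i, ] <- ifelse(m[i, ], acc, 0L)
  }
  # propagate the run maximum backwards within each run
  for (i in rev(seq_len(d[1] - 1L))) {
    carry <- m[i, ] & m[i + 1L, ]
    run[i, ] <- ifelse(carry, pmax(run[i, ], run[i + 1L, ]), run[i, ])
  }
  dim(run) <- d
  aperm(run, inv)
}

# 6-connectivity components of a logical 3-D mask; returns integer labels
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  strides <- c(1L, d[1], d[1] * d[2])
  cand <- which(mask)
  if (!length(cand)) return(lab)
  cur <- 0L
  inmask <- mask
  for (seed in cand) {
    if (lab[seed] > 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      ci <- arrayInd(frontier, d)
      nb <- integer(0)
      for (ax in 1:3) for (dlt in c(-1L, 1L)) {
        ok <- ci[, ax] + dlt >= 1L & ci[, ax] + dlt <= d[ax]
        nb <- c(nb, frontier[ok] + dlt * strides[ax])
      }
      nb <- unique(nb)
      nb <- nb[inmask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# in-plane 4-neighbour erosion, slice by slice
erode_inplane <- function(mask) {
  d <- dim(mask)
  out <- mask
  sh <- function(m, di, dj) {
    r <- array(FALSE, dim(m))
    i1 <- max(1, 1 + di):min(d[1], d[1] + di)
    j1 <- max(1, 1 + dj):min(d[2], d[2] + dj)
    r[i1, j1, ] <- m[i1 - di, j1 - dj, ]
    r
  }
  out & sh(mask, 1, 0) & sh(mask, -1, 0) & sh(mask, 0, 1) & sh(mask, 0, -1)
}

#' Body mask on the reconstruction grid
#'
#' Downsamples the truth body label to the reconstruction grid (majority
#' vote) and erodes by one voxel in-plane, the volume of interest for
#' per-slice SUV measurement.
#'
#' @param truth a `phantom_truth`.
#' @param geometry a `scan_geometry`.
#' @param image_voxel reconstruction voxel size, mm.
#' @return logical array on the reconstruction grid.
#' @export
body_mask_on_recon <- function(truth, geometry, image_voxel = 4) {
  lb <- truth$labels
  frac <- lb; frac$values <- (lb$values == LBL_BODY) * 1
  frac$quantity <- "activity"
  f <- c(image_voxel / lb$voxel_size[1:2], geometry$slice_thickness / lb$voxel_size[3])
  coarse <- block_average(frac, as.integer(round(f)))
  n <- as.integer(round(geometry$fov / image_voxel))
  coarse <- embed_volume(coarse, c(n, n, dim(coarse$values)[3]),
                         c(rep(-(n - 1) / 2 * image_voxel, 2), coarse$origin[3]))
  erode_inplane(coarse$values > 0.5)
}

# axial slice range (on the data slices) occupied by each catheter label
label_slice_ranges <- function(truth, geometry) {
  lb <- truth$labels$values
  zc <- voxel_centers(truth$labels, 3)
  st <- geometry$slice_thickness
  labs <- sort(setdiff(unique(as.vector(lb)), c(LBL_AIR, LBL_BODY, LBL_WALL)))
  out <- lapply(labs, function(l) {
    zz <- zc[apply(lb == l, 3, any)]
    sl <- unique(pmin(pmax(floor(zz / st) + 1L, 1L), truth$n_slices))
    range(sl)
  })
  data.frame(label = labs,
             name = label_table()$name[match(labs, label_table()$label)],
             slice_min = vapply(out, function(r) as.integer(r[1]), integer(1)),
             slice_max = vapply(out, function(r) as.integer(r[2]), integer(1)))
}

# ---- halo detection --------------------------------------------------------

#' Detect halo artifacts
#'
#' Implements the two-step rule: (1) find cold regions as axis-aligned runs of
#' at least `min_run` consecutive voxels with SUV at or below `zero_epsilon`
#' in the scatter-corrected image, merged into 6-connected regions; (2) keep
#' only regions whose mean value in the non-scatter-corrected image exceeds
#' `nsc_floor` (genuinely cold tissue is cold in both).
#'
#' @param sc scatter-corrected SUV `voxel_volume`.
#' @param nsc non-scatter-corrected SUV `voxel_volume`, same grid.
#' @param zero_epsilon SUV treated as zero.
#' @param min_run minimum run of consecutive near-zero voxels.
#' @param nsc_floor minimum NSC mean for a region to count as an artifact.
#' @param roi optional logical array restricting the search (e.g. the body
#'   volume of interest).
#' @return data frame with one row per halo region: size (voxels), slice
#'   range, centroid, and NSC mean; voxel indices in attribute `"voxels"`.
#' @export
detect_halo <- function(sc, nsc, zero_epsilon = 0.01, min_run = 3L,
                        nsc_floor = 0.1, roi = NULL) {
  if (!identical(dim(sc$values), dim(nsc$values)))
    stop("sc and nsc grids differ")
  cold <- sc$values <= zero_epsilon
  if (!is.null(roi)) cold <- cold & roi
  keep <- array(FALSE, dim(cold))
  for (ax in 1:3)
    keep <- keep | run_lengths_along(cold, ax) >= min_run
  lab <- label_components(keep)
  n <- max(lab)
  empty <- data.frame(region = integer(0), size = integer(0),
                      slice_min = integer(0), slice_max = integer(0),
                      x_mm = numeric(0), y_mm = numeric(0),
                      nsc_mean = numeric(0))
  if (n == 0L) return(structure(empty, voxels = list()))
  rows <- list(); vox <- list()
  d <- dim(lab)
  for (r in seq_len(n)) {
    idx <- which(lab == r)
    ci <- arrayInd(idx, d)
    nm <- mean(nsc$values[idx])
    if (nm <= nsc_floor) next
    rows[[length(rows) + 1L]] <- data.frame(
      region = length(rows) + 1L, size = length(idx),
      slice_min = min(ci[, 3]), slice_max = max(ci[, 3]),
      x_mm = sc$origin[1] + (mean(ci[, 1]) - 1) * sc$voxel_size[1],
      y_mm = sc$origin[2] + (mean(ci[, 2]) - 1) * sc$voxel_size[2],
      nsc_mean = nm)
    vox[[length(vox) + 1L]] <- idx
  }
  if (!length(rows)) return(structure(empty, voxels = list()))
  structure(do.call(rbind, rows), voxels = vox)
}

#' Per-slice mean SUV
#'
#' Mean SUV inside the body volume of interest, slice by slice; slices with an
#' empty mask are omitted (not reported as zero).
#'
#' @param image SUV `voxel_volume`.
#' @param body_mask logical array on the same grid.
#' @return data frame with `slice`, `z_mm`, `mean_suv`.
#' @export
suv_per_slice <- function(image, body_mask) {
  if (!identical(dim(image$values), dim(body_mask)))
    stop("image and mask grids differ")
  nz <- dim(image$values)[3]
  res <- lapply(seq_len(nz), function(j) {
    m <- body_mask[, , j]
    if (!any(m)) return(NULL)
    data.frame(slice = j,
               z_mm = image$origin[3] + (j - 1) * image$voxel_size[3],
               mean_suv = mean(image$values[, , j][m]))
  })
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}

#' Radial sinogram profiles
#'
#' Extracts the radial profile of several sinograms at one slice and
#' projection angle, together with the tail-mask extent - the view used to
#' compare measured emission with each scatter estimate.
#'
#' @param sinos named list of `sinogram`s sharing geometry.
#' @param mask optional [tail_mask].
#' @param slice slice index.
#' @param angle angle index.
#' @return data frame with `bin`, `s_mm`, `tail`, one column per sinogram.
#' @export
sinogram_profiles <- function(sinos, mask = NULL, slice = 1L, angle = 1L) {
  g <- sinos[[1]]$geometry
  for (s in sinos)
    if (!identical(dim(s$values)[1:2], c(g$n_radial, g$n_angles)))
      stop("sinograms do not share geometry")
  if (slice < 1L || slice > dim(sinos[[1]]$values)[3] ||
      angle < 1L || angle > g$n_angles)
    stop("slice or angle out of range")
  out <- data.frame(bin = seq_len(g$n_radial), s_mm = radial_centers(g))
  out$tail <- if (is.null(mask)) NA else mask$mask[, angle, slice]
  for (nm in names(sinos))
    out[[nm]] <- sinos[[nm]]$values[, angle, slice]
  out
}

# ---- experiment driver -----------------------------------------------------

embed_fov <- function(vol, n, voxel) {
  embed_volume(vol, c(n, n, dim(vol$values)[3]),
               c(rep(-(n - 1) / 2 * voxel, 2), vol$origin[3]))
}

# trues and reconstruction-side ACF handling sub-slice (finer axial) grids:
# trues are generated per sub-slice and summed; ACF averages the line
# integrals of the sub-slices of each data slice
combine_subslices <- function(arr, fz, how = c("sum", "mean")) {
  how <- match.arg(how)
  if (fz == 1L) return(arr)
  d <- dim(arr)
  ns <- d[3] %/% fz
  dim(arr) <- c(d[1] * d[2], fz, ns)
  out <- apply(arr, c(1, 3), sum)
  if (how == "mean") out <- out / fz
  array(out, c(d[1], d[2], ns))
}

acf_from_mumap <- function(mumap, geometry) {
  li <- forward_project(mumap, geometry, "mu_line_integral")
  fz <- as.integer(round(geometry$slice_thickness / mumap$voxel_size[3]))
  v <- combine_subslices(li$values / 10, fz, "mean")
  sinogram(exp(v), geometry, "acf")
}

#' Run a full phantom experiment
#'
#' The whole pipeline for one phantom pattern: phantom generation, mu-map
#' preparation at 4 mm and 2 mm, noiseless trues plus Monte-Carlo scatter as
#' the measured prompts, single-scatter estimation, per-method scatter scaling
#' (no correction, tail-fitted at either mu-map size, Monte-Carlo-scaled),
#' OSEM reconstruction, SUV calibration, per-slice SUV curves, and halo
#' detection against the NSC reference.
#'
#' @param config a [run_config].
#' @param verbose print stage progress.
#' @return object of class `experiment_report`: per-method SUV volumes
#'   (`suv`), per-slice SUV table (`suv_table`), halo regions (`halos`),
#'   per-slice scale factors and scatter fractions, catheter label slice
#'   ranges, tail masks, prompts/trues/scatter sinograms, a slim phantom
#'   summary (`truth`: spec plus lumen centroids; the fine-grid volumes are
#'   not retained), and the config.
#' @export
run_experiment <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  g <- config_geometry(config)
  n_img <- as.integer(round(g$fov / config$image_voxel))
  set <- recon_settings(config$iterations, config$subsets,
                        config$image_voxel, config$scatter_mode)
  cs <- config$count_scale

  say("phantom: %s", config$pattern)
  spec <- do.call(phantom_spec, c(list(pattern = config$pattern), config$phantom))
  truth <- make_phantom(spec, seed = derive_seed(config$seed, "phantom"))
  pair <- mismatch_pair(truth)
  nsl <- truth$n_slices

  # data-generation grid: 2-mm in-plane, truth axial planes block-averaged to
  # 2-mm sub-slices (two per 4-mm data slice)
  f_sim <- as.integer(round(2 / truth$activity$voxel_size))
  act_sim <- embed_fov(block_average(pair$activity_for_pet, f_sim), g$fov / 2, 2)
  att_sim <- embed_fov(block_average(pair$attenuation_for_pet, f_sim), g$fov / 2, 2)
  fz_sim <- as.integer(round(g$slice_thickness / act_sim$voxel_size[3]))

  say("trues")
  tr_sub <- simulate_trues(act_sim, att_sim, g, count_scale = cs / fz_sim)
  trues <- sinogram(combine_subslices(tr_sub$values, fz_sim, "sum"), g, "trues")

  say("Monte-Carlo scatter (%g decays)", config$n_decays)
  mc <- mc_transport(act_sim, att_sim, g, n_decays = config$n_decays,
                     max_scatter_order = config$max_scatter_order,
                     axial_acceptance = config$scatter_axial_acceptance,
                     seed = derive_seed(config$seed, "mc"))
  rm(tr_sub, act_sim, att_sim); gc(FALSE)
  mc_tr <- combine_subslices(mc$trues$values, fz_sim, "sum")
  mc_sc <- combine_subslices(mc$scatter$values, fz_sim, "sum")
  per <- mc$tallies$per_slice
  grp <- rep(seq_len(nsl), each = fz_sim)
  nt_sl <- tapply(per$n_true, grp, sum)
  ns_sl <- tapply(per$n_scattered, grp, sum)
  sf_sl <- ifelse(nt_sl + ns_sl > 0, ns_sl / (nt_sl + ns_sl), 0)

  sc_sm <- smooth_sinogram(sinogram(mc_sc, g, "scatter"), config$mc_smooth_bins)
  anchor <- vapply(seq_len(nsl), function(j) {
    mt <- sum(mc_tr[, , j])
    if (mt > 0) sum(trues$values[, , j]) / mt else 0
  }, numeric(1))
  scat_true <- sc_sm$values * rep(anchor, each = g$n_radial * g$n_angles)
  prompts <- sinogram(trues$values + scat_true, g, "prompts")
  if (config$poisson)
    prompts <- add_poisson(prompts, derive_seed(config$seed, "poisson"))

  say("mu-maps")
  need4 <- any(c("NSC", "TFS4", "MCS4") %in% config$methods)
  need2 <- "TFS2" %in% config$methods
  mumap4 <- if (need4) prepare_mumap(pair$attenuation_for_ct, 4,
                                     config$mumap_fwhm, fov = g$fov)
  mumap2 <- if (need2) prepare_mumap(pair$attenuation_for_ct, 2,
                                     config$mumap_fwhm, fov = g$fov)
  acf4 <- if (need4) acf_from_mumap(mumap4, g)
  acf2 <- if (need2) acf_from_mumap(mumap2, g)
  bmask <- body_mask_on_recon(truth, g, config$image_voxel)
  lranges <- label_slice_ranges(truth, g)
  # the fine-grid volumes are no longer needed: keep only the spec and the
  # catheter's geometric fingerprint so a session can hold several reports
  # without exhausting memory
  truth <- structure(list(spec = truth$spec, n_slices = truth$n_slices,
                          lumen_centroids = lumen_centroids(truth)),
                     class = "phantom_truth")
  rm(pair); gc(FALSE)

  say("NSC reconstruction")
  zeros <- build_scatter_estimate("NSC", geometry = g, n_slices = nsl)
  acf_nsc <- if (need4) acf4 else acf2
  nsc_img <- osem(prompts, acf_nsc, zeros, g, set, count_scale = cs)

  say("single-scatter simulation")
  sss4 <- if (any(c("TFS4", "MCS4") %in% config$methods))
    sss_estimate(nsc_img, mumap4, g, grid_spacing = config$sss_grid_spacing,
                 count_scale = cs, n_directions = config$sss_n_directions,
                 slice_stride = config$sss_stride,
                 smoothing_fwhm_bins = config$sss_smooth_bins,
                 axial_acceptance = config$scatter_axial_acceptance)
  sss2 <- if (need2)
    sss_estimate(nsc_img, mumap2, g, grid_spacing = config$sss_grid_spacing,
                 count_scale = cs, n_directions = config$sss_n_directions,
                 slice_stride = config$sss_stride,
                 smoothing_fwhm_bins = config$sss_smooth_bins,
                 axial_acceptance = config$scatter_axial_acceptance)

  masks <- list()
  if (any(c("TFS4") %in% config$methods))
    masks$`4` <- tail_mask(mumap4, g, method = config$mask_method,
                           threshold = config$mask_threshold,
                           dilate_bins = config$mask_dilate_bins)
  if (need2)
    masks$`2` <- tail_mask(mumap2, g, method = config$mask_method,
                           threshold = config$mask_threshold,
                           dilate_bins = config$mask_dilate_bins)

  sf_mcs <- NULL
  if ("MCS4" %in% config$methods) {
    if (config$sf_source == "truth") {
      sf_mcs <- sf_sl
    } else {
      say("scatter-fraction estimate on reconstruction-side volumes")
      att_est <- mumap4
      est <- mc_transport(nsc_img, att_est, g,
                          n_decays = config$sf_estimate_decays,
                          max_scatter_order = config$max_scatter_order,
                          axial_acceptance = config$scatter_axial_acceptance,
                          seed = derive_seed(config$seed, "sf_estimate"))
      pe <- est$tallies$per_slice
      sf_mcs <- ifelse(pe$n_true + pe$n_scattered > 0,
                       pe$n_scattered / (pe$n_true + pe$n_scattered), 0)
    }
  }

  estimates <- list()
  for (m in config$methods) {
    estimates[[m]] <- switch(m,
      NSC = zeros,
      TFS4 = build_scatter_estimate("TFS", sss = sss4, emission = prompts,
                                    mask = masks$`4`, mumap_voxel = 4,
                                    on_empty = "zero"),
      TFS2 = build_scatter_estimate("TFS", sss = sss2, emission = prompts,
                                    mask = masks$`2`, mumap_voxel = 2,
                                    on_empty = "zero"),
      MCS4 = build_scatter_estimate("MCS", sss = sss4, emission = prompts,
                                    sf = sf_mcs, mumap_voxel = 4))
  }

  say("reconstructions")
  suvs <- list()
  for (m in config$methods) {
    acf_m <- if (m == "TFS2") acf2 else acf_nsc
    img <- if (m == "NSC") nsc_img else
      osem(prompts, acf_m, estimates[[m]], g, set, count_scale = cs)
    suvs[[m]] <- calibrate_suv(img, config$calibration_reference)
  }

  say("analysis")
  suv_tab <- NULL
  for (m in config$methods) {
    t <- suv_per_slice(suvs[[m]], bmask)
    t$method <- m
    suv_tab <- rbind(suv_tab, t)
  }
  halos <- list()
  if ("NSC" %in% config$methods) {
    for (m in setdiff(config$methods, "NSC"))
      halos[[m]] <- detect_halo(suvs[[m]], suvs$NSC,
                                zero_epsilon = config$zero_epsilon,
                                min_run = config$min_run,
                                nsc_floor = config$nsc_floor, roi = bmask)
  }
  scale_tab <- data.frame(slice = seq_len(nsl))
  for (m in config$methods) scale_tab[[m]] <- estimates[[m]]$scale_k
  scale_tab$scatter_fraction <- as.numeric(sf_sl)

  structure(list(
    config = config, pattern = config$pattern, geometry = g,
    truth = truth, body_mask = bmask,
    label_ranges = lranges,
    prompts = prompts, trues = trues,
    scatter_truth = sinogram(scat_true, g, "scatter"),
    sss = list(`4` = sss4, `2` = sss2), masks = masks,
    estimates = estimates, suv = suvs,
    suv_table = suv_tab, halos = halos, scale_table = scale_tab,
    tallies = mc$tallies
  ), class = "experiment_report")
}

#' @exportS3Method base::print
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> pattern %s\n", x$pattern))
  for (m in names(x$halos)) {
    h <- x$halos[[m]]
    cat(sprintf("  %s: %d halo region(s)%s\n", m, nrow(h),
                if (nrow(h)) sprintf(" (largest %d voxels, slices %d-%d)",
                                     max(h$size), h$slice_min[which.max(h$size)],
                                     h$slice_max[which.max(h$size)]) else ""))
  }
  agg <- stats::aggregate(mean_suv ~ method, data = x$suv_table, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  body-VOI mean SUV %s: %.3f\n", agg$method[i], agg$mean_suv[i]))
  invisible(x)
}

#' Summarize per-slice SUV over a slice range
#'
#' @param report an `experiment_report`.
#' @param slices slice indices (default: all with data).
#' @return data frame with method, mean and sd of per-slice mean SUV, n.
#' @export
suv_summary <- function(report, slices = NULL) {
  t <- report$suv_table
  if (!is.null(slices)) t <- t[t$slice %in% slices, ]
  agg <- stats::aggregate(mean_suv ~ method, data = t,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  data.frame(method = agg$method,
             mean = agg$mean_suv[, "mean"],
             sd = agg$mean_suv[, "sd"],
             n = agg$mean_suv[, "n"])
}
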