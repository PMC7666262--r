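# shared small fixtures: a water disk on the default scanner grid, and
# memoised full experiments (computed once per test session)

default_geometry <- function() scan_geometry()

# n x n FOV-spanning disk volumes (activity kBq/mL, attenuation 1/cm)
disk_volumes <- function(radius = 100, n = 144, voxel = 4, activity = 3,
                         mu = 0.096, n_slices = 1) {
  cx <- (seq_len(n) - (n + 1) / 2) * voxel
  d2 <- outer(cx, cx, function(x, y) x^2 + y^2)
  disk <- d2 <= radius^2
  org <- c(cx[1], cx[1], 2)
  list(
    activity = voxel_volume(array(rep(disk * activity, n_slices),
                                  c(n, n, n_slices)),
                            c(voxel, voxel, 4), org, "activity"),
    attenuation = voxel_volume(array(rep(disk * mu, n_slices),
                                     c(n, n, n_slices)),
                               c(voxel, voxel, 4), org, "attenuation"),
    disk = disk, d2 = d2, centers = cx
  )
}

.exp_cache <- new.env(parent = emptyenv())

# full desk-geometry experiment, memoised per pattern (used by the acceptance
# tests: one computation serves several criteria)
get_experiment <- function(pattern, seed = 1L) {
  key <- paste0(pattern, "_", seed)
  if (is.null(.exp_cache[[key]])) {
    cfg <- if (pattern == "none")
      run_config(pattern = "none", seed = seed,
                 phantom = list(body_length = 12),
                 methods = c("NSC", "TFS4", "TFS2", "MCS4"))
    else run_config(pattern = pattern, seed = seed)
    .exp_cache[[key]] <- run_experiment(cfg)
  }
  .exp_cache[[key]]
}

# slice range of a catheter label in a report
label_slices <- function(report, label) {
  r <- report$label_ranges
  i <- match(label, r$label)
  r$slice_min[i]:r$slice_max[i]
}
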