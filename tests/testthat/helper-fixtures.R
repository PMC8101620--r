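# Shared lazily-built fixtures. Expensive phantoms and pipeline runs are
# memoised in one environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# membership volume wrapper around a raw array (already in [0,1])
mk_membership <- function(arr, h = 1) {
  structure(list(values = arr, spacing = rep(h, 3),
                 marrow_ref = 0, bone_ref = 1),
            class = "membership_volume")
}

# skeleton_map wrapper around a hand-built thin mask
mk_skeleton <- function(mask, h = 1) {
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask,
                 voxels = tibble::tibble(x = idx[, 1], y = idx[, 2],
                                         z = idx[, 3],
                                         membership = 1,
                                         fdt = h / 2),
                 spacing = rep(h, 3)),
            class = "skeleton_map")
}

full_roi <- function(dims, h = 0.15) {
  roi_mask(array(TRUE, dims), rep(h, 3))
}

box_roi <- function(dims, margin, h = 0.15) {
  m <- array(FALSE, dims)
  m[(1 + margin):(dims[1] - margin), (1 + margin):(dims[2] - margin),
    (1 + margin):(dims[3] - margin)] <- TRUE
  roi_mask(m, rep(h, 3))
}

# the standard tibia phantoms and pipeline runs (shared by the pipeline
# smoke tests and the acceptance suite)
tibia_run <- function(tilt) {
  key <- paste0("tibia_run_", tilt)
  fixture(key, {
    tp <- make_tibia_phantom(seed = 2, tilt_deg = tilt)
    cfg <- pipeline_config(tibial_length_mm = tp$truth$tibial_length_mm,
                           marrow_ref = 100)
    list(phantom = tp, result = run_pipeline(tp$volume, cfg))
  })
}

metrics_wide <- function(res) {
  tidyr::pivot_wider(res$metrics, names_from = "measure",
                     values_from = "value")
}
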