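#' Propagate MR contours to every 4D-CT phase
#'
#' Three methods share one contract: estimate, for each respiratory phase,
#' a single end-to-end deformation from the native MR frame to that phase's
#' CT frame, and transport the MR organ labels through it.
#'
#' * `propagate_rigid()` — the clinical baseline: the rigid mutual-information
#'   pre-alignment alone, identical for every phase (no motion
#'   compensation).
#' * `propagate_direct()` — one multi-modal network maps the (rigidly
#'   pre-aligned) MR to each CT phase directly; the predicted field is
#'   composed with the rigid field.
#' * `propagate_pipeline()` — two-step decomposition: a multi-modal network
#'   maps MR to the reference CT-50, a temporal mono-modal network maps
#'   CT-50 to each phase, and the final field is the composition
#'   (rigid, then multi-modal, then temporal).
#'
#' Deformable fields are predicted at the network working resolution and
#' trilinearly upsampled to the native grid before label warping; labels
#' are warped nearest-neighbour at native resolution.
#'
#' @param study a [make_study()] study (or a compatible record with `mr`,
#'   `ct`, `labels_mr`, `grid`).
#' @param net_multi,net_mono,net_direct trained [build_network()] networks.
#' @param seed seed for the rigid optimizer restarts.
#' @param rigid optionally, a precomputed [rigid_align()] result to reuse.
#' @return An object of class `mr4dct_result`: `method`, `fields` (named
#'   list phase -> [displacement_field()] on the native grid),
#'   `warped_labels` (phase -> [label_map()]), `warped_mr` (phase ->
#'   [volume()], normalized intensities), `omega`, `rigid`, `runtime_s`,
#'   `per_phase_s`.
#' @name propagate
NULL

prep_native <- function(study, seed, rigid = NULL) {
  g <- study$grid
  mrn <- normalize_intensities(study$mr)
  mr_ct <- resample_to_grid(mrn, g)
  support <- support_mask(study$mr, g)
  ct50n <- normalize_intensities(study$ct[["50"]])
  if (is.null(rigid)) {
    rigid <- rigid_align(mr_ct, ct50n, seed = seed, support = support)
  }
  lab_mr_ct <- resample_to_grid(study$labels_mr, g, "nearest")
  list(g = g, mr_ct = mr_ct, support = support, ct50n = ct50n,
       rigid = rigid, lab_mr_ct = lab_mr_ct)
}

finish_result <- function(method, study, prep, fields, t0, per_phase) {
  warped_labels <- lapply(fields, function(f) {
    warp(prep$lab_mr_ct, f, "nearest")
  })
  warped_mr <- lapply(fields, function(f) {
    warp(prep$mr_ct, f, "trilinear")
  })
  structure(list(method = method, fields = fields,
                 warped_labels = warped_labels, warped_mr = warped_mr,
                 omega = prep$rigid$omega, rigid = prep$rigid,
                 runtime_s = as.numeric(Sys.time() - t0, units = "secs"),
                 per_phase_s = per_phase),
            class = "mr4dct_result")
}

#' @rdname propagate
#' @export
propagate_rigid <- function(study, seed = 0L, rigid = NULL) {
  t0 <- Sys.time()
  prep <- prep_native(study, seed, rigid)
  keys <- as.character(study$phases)
  fields <- setNames(lapply(keys, function(k) prep$rigid$field), keys)
  per_phase <- setNames(rep(0, length(keys)), keys)
  finish_result("rigid", study, prep, fields, t0, per_phase)
}

# predict a deformable field at working resolution for (fixed, moving)
# native arrays, integrate, and upsample to the native grid
predict_field_native <- function(net, fixed_arr, moving_arr, native_grid) {
  wg <- net$cfg$input_grid
  f_w <- resample_array(fixed_arr, native_grid, wg)
  m_w <- resample_array(moving_arr, native_grid, wg)
  v <- predict_svf(net, volume(f_w, wg), volume(m_w, wg))
  phi_w <- integrate_svf(v)
  upsample_field(phi_w, native_grid)
}

#' @rdname propagate
#' @export
propagate_direct <- function(study, net_direct, seed = 0L, rigid = NULL) {
  t0 <- Sys.time()
  prep <- prep_native(study, seed, rigid)
  check_near_identity(net_direct)
  mr_rigid <- warp(prep$mr_ct, prep$rigid$field, "trilinear")
  keys <- as.character(study$phases)
  fields <- list()
  per_phase <- numeric(length(keys))
  for (i in seq_along(keys)) {
    tp <- Sys.time()
    k <- keys[i]
    ctn <- normalize_intensities(study$ct[[k]])
    phi_d <- predict_field_native(net_direct, ctn$data, mr_rigid$data,
                                  prep$g)
    fields[[k]] <- compose_fields(prep$rigid$field, phi_d)
    per_phase[i] <- as.numeric(Sys.time() - tp, units = "secs")
  }
  finish_result("direct", study, prep, fields, t0,
                setNames(per_phase, keys))
}

#' @rdname propagate
#' @export
propagate_pipeline <- function(study, net_multi, net_mono, seed = 0L,
                               rigid = NULL) {
  t0 <- Sys.time()
  prep <- prep_native(study, seed, rigid)
  check_near_identity(net_multi)
  check_near_identity(net_mono)
  mr_rigid <- warp(prep$mr_ct, prep$rigid$field, "trilinear")
  phi_multi <- predict_field_native(net_multi, prep$ct50n$data,
                                    mr_rigid$data, prep$g)
  phi_mr_ct50 <- compose_fields(prep$rigid$field, phi_multi)
  keys <- as.character(study$phases)
  fields <- list()
  per_phase <- numeric(length(keys))
  for (i in seq_along(keys)) {
    tp <- Sys.time()
    k <- keys[i]
    ctn <- normalize_intensities(study$ct[[k]])
    phi_t <- predict_field_native(net_mono, ctn$data, prep$ct50n$data,
                                  prep$g)
    fields[[k]] <- compose_fields(phi_mr_ct50, phi_t)
    per_phase[i] <- as.numeric(Sys.time() - tp, units = "secs")
  }
  finish_result("pipeline", study, prep, fields, t0,
                setNames(per_phase, keys))
}

# warn when a network looks untrained (near-zero output layer)
check_near_identity <- function(net) {
  if (max(abs(net$params$head$w)) < 1e-4) {
    warn(paste0("network output layer is near zero (untrained?); ",
                "predicted fields will be near-identity"))
  }
  invisible(net)
}

#' @export
print.mr4dct_result <- function(x, ...) {
  cat(sprintf("<%s propagation: %d phases, %.2f s total>\n", x$method,
              length(x$fields), x$runtime_s))
  invisible(x)
}

#' Export a propagation result to NIfTI files
#'
#' Writes one label map and one displacement field per phase plus a JSON
#' manifest.
#'
#' @param result a `mr4dct_result`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (k in names(result$fields)) {
    lp <- file.path(dir, sprintf("labels_phase_%s.nii.gz", k))
    fp <- file.path(dir, sprintf("field_phase_%s.nii.gz", k))
    write_volume(result$warped_labels[[k]], lp)
    write_field(result$fields[[k]], fp)
    entries[[k]] <- list(labels = basename(lp), field = basename(fp))
  }
  manifest <- file.path(dir, "result.json")
  jsonlite::write_json(list(method = result$method,
                            runtime_s = result$runtime_s,
                            phases = names(result$fields),
                            files = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
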