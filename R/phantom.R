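#' Configuration of the synthetic 4D dual-modality phantom
#'
#' The phantom stands in for a clinical liver-SBRT study: one CT-like volume
#' per respiratory phase with smooth diffeomorphic motion that vanishes at
#' the 50% (end-expiration) reference phase, a companion MR-like volume with
#' genuinely different per-organ contrast, a reduced MR field of view, a
#' known rigid misalignment between the modalities, and optional 4D-CT
#' binning artifacts. All randomness is seeded; every artifact of
#' [make_study()] is bit-for-bit reproducible.
#'
#' @param grid a [grid3()]; desk-scale default 48x48x32 at 2 mm.
#' @param organs subset of the built-in organ set to include.
#' @param amplitude peak superior-inferior diaphragm excursion, mm.
#' @param phases respiratory phase percentages; must include 50.
#' @param mr_fov_crop fraction of the z-extent retained in the MR volume.
#' @param mr_misalignment [rigid_params()]: the ground-truth rigid transform
#'   that maps the native (misaligned) MR onto the CT frame — i.e. what
#'   [rigid_align()] should recover.
#' @param artifact_rate per-phase probability of a duplicated-slab binning
#'   artifact.
#' @param noise_sd intensity texture standard deviation (HU-like).
#' @param seed integer seed.
#' @return A list of class `mr4dct_phantom_config`.
#' @export
phantom_config <- function(grid = grid3(c(48, 48, 32), c(2, 2, 2)),
                           organs = phantom_organs()$name,
                           amplitude = 10,
                           phases = c(0, 16, 33, 50, 66, 83),
                           mr_fov_crop = 0.75,
                           mr_misalignment = rigid_params(c(6, -4, 8)),
                           artifact_rate = 0,
                           noise_sd = 15,
                           seed = 0L) {
  assert_that(amplitude >= 0, "amplitude must be >= 0")
  assert_that(mr_fov_crop > 0 && mr_fov_crop <= 1,
              "mr_fov_crop must be in (0, 1]")
  assert_that(50 %in% phases, "phases must include the 50% reference")
  assert_that(artifact_rate >= 0 && artifact_rate <= 1,
              "artifact_rate must be in [0, 1]")
  structure(list(grid = grid, organs = organs, amplitude = amplitude,
                 phases = phases, mr_fov_crop = mr_fov_crop,
                 mr_misalignment = mr_misalignment,
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mr4dct_phantom_config")
}

#' Built-in phantom organ table
#'
#' Geometry in normalized torso coordinates (x right-to-left, y
#' anterior-to-posterior, z inferior-to-superior), CT attenuation (HU-like)
#' and MR signal (arbitrary units). The MR column is deliberately *not* a
#' monotone remap of the CT column — their rank correlation is low — so
#' cross-modality similarity genuinely requires mutual information. Voxels
#' claimed by several shapes are resolved by precedence (higher wins).
#'
#' @return A tibble with one row per organ.
#' @export
phantom_organs <- function() {
  tibble::tribble(
    ~organ_id, ~name,        ~hu,   ~mr,  ~precedence, ~supervised,
    1L, "liver",      60,   0.75, 2, TRUE,
    2L, "spleen",     50,   0.45, 4, TRUE,
    3L, "kidney_L",   35,   0.65, 5, TRUE,
    4L, "kidney_R",   35,   0.65, 5, TRUE,
    5L, "lung_L",    -700,  0.05, 3, FALSE,
    6L, "lung_R",    -700,  0.05, 3, FALSE,
    7L, "heart",      45,   0.50, 4, FALSE,
    8L, "stomach",    25,   0.35, 4, FALSE,
    9L, "vertebrae",  400,  0.25, 6, FALSE,
    10L, "body",      40,   0.55, 1, FALSE
  )
}

# normalized coordinate arrays (voxel center i / (n - 1))
norm_coords <- function(shape) {
  nx <- if (shape[1] > 1) (seq_len(shape[1]) - 1) / (shape[1] - 1) else 0.5
  ny <- if (shape[2] > 1) (seq_len(shape[2]) - 1) / (shape[2] - 1) else 0.5
  nz <- if (shape[3] > 1) (seq_len(shape[3]) - 1) / (shape[3] - 1) else 0.5
  list(x = array(nx, shape),
       y = aperm(array(ny, shape[c(2, 1, 3)]), c(2, 1, 3)),
       z = aperm(array(nz, shape[c(3, 1, 2)]), c(2, 3, 1)))
}

ellipsoid_mask <- function(nc, center, semi) {
  ((nc$x - center[1]) / semi[1])^2 + ((nc$y - center[2]) / semi[2])^2 +
    ((nc$z - center[3]) / semi[3])^2 <= 1
}

# The abdominal organs sit in the upper two thirds of the volume so the
# inferior motion ramp-off (below z ~ 0.26) runs through organ-free tissue:
# keeping labelled structures out of the high-velocity-gradient zone keeps
# ground-truth label transport interpolation-limited. Per-subject anatomical
# variation comes from seeded jitter of organ centers (up to 0.02 of the
# normalized extent) and sizes (up to 6%), small enough to respect the
# motion-zone layout above.
phantom_geometry <- function(nc, seed = NULL) {
  centers <- list(
    liver = c(0.35, 0.45, 0.55), spleen = c(0.74, 0.60, 0.50),
    kidney_L = c(0.64, 0.68, 0.44), kidney_R = c(0.36, 0.68, 0.44),
    lung_L = c(0.68, 0.45, 0.82), lung_R = c(0.32, 0.45, 0.82),
    heart = c(0.52, 0.38, 0.78), stomach = c(0.65, 0.32, 0.52))
  semis <- list(
    liver = c(0.22, 0.24, 0.15), spleen = c(0.09, 0.10, 0.09),
    kidney_L = c(0.07, 0.08, 0.10), kidney_R = c(0.07, 0.08, 0.10),
    lung_L = c(0.15, 0.19, 0.14), lung_R = c(0.16, 0.20, 0.14),
    heart = c(0.13, 0.13, 0.10), stomach = c(0.12, 0.10, 0.10))
  if (!is.null(seed)) {
    jit <- with_seed(derive_seed(seed, 71), {
      lapply(seq_along(centers), function(i) {
        list(dc = runif(3, -0.02, 0.02), ds = runif(1, 0.94, 1.06))
      })
    })
    for (i in seq_along(centers)) {
      centers[[i]] <- centers[[i]] + jit[[i]]$dc
      semis[[i]] <- semis[[i]] * jit[[i]]$ds
    }
  }
  body <- ((nc$x - 0.5) / 0.42)^2 + ((nc$y - 0.5) / 0.38)^2 <= 1 &
    nc$z >= 0.04 & nc$z <= 0.98
  out <- lapply(names(centers), function(nm) {
    ellipsoid_mask(nc, centers[[nm]], semis[[nm]])
  })
  names(out) <- names(centers)
  out$body <- body
  out$vertebrae <- ((nc$x - 0.5) / 0.07)^2 + ((nc$y - 0.78) / 0.08)^2 <= 1 &
    nc$z >= 0.04 & nc$z <= 0.98
  out
}

#' Generate the reference-phase anatomy
#'
#' Smooth ellipsoid organs at plausible relative positions inside a body
#' contour; per-organ CT intensity is a tabulated HU-like mean plus seeded
#' Gaussian texture. Labels are exactly the generating supports, with
#' overlaps resolved by the fixed precedence order.
#'
#' @param cfg a [phantom_config()].
#' @return List with `ct50` (a [volume()], HU-like) and `labels` (a
#'   [label_map()]).
#' @export
make_anatomy <- function(cfg) {
  stopifnot(inherits(cfg, "mr4dct_phantom_config"))
  organs <- phantom_organs()
  organs <- organs[organs$name %in% cfg$organs, ]
  nc <- norm_coords(cfg$grid$shape)
  geo <- phantom_geometry(nc, seed = cfg$seed)
  shp <- cfg$grid$shape
  lab <- array(0L, shp)
  # organs restricted to the body; precedence order resolves ownership
  for (i in order(organs$precedence)) {
    nm <- organs$name[i]
    m <- geo[[nm]] & geo$body
    lab[m] <- organs$organ_id[i]
  }
  hu <- array(-1000, shp)
  for (i in seq_len(nrow(organs))) {
    hu[lab == organs$organ_id[i]] <- organs$hu[i]
  }
  hu <- with_seed(derive_seed(cfg$seed, 11), {
    tex <- array(rnorm(prod(shp), sd = cfg$noise_sd), shp)
    hu + tex * (lab > 0)
  })
  registry <- organ_registry(organs$organ_id, organs$name,
                             supervised = organs$supervised,
                             full_fov = TRUE)
  list(ct50 = volume(hu, cfg$grid, "CT", phase = 50),
       labels = label_map(lab, cfg$grid, registry))
}

# respiratory amplitude factor: 1 at 0% (peak inhalation side), 0 at 50%
phase_amplitude <- function(phase_pct) {
  (cos(2 * pi * phase_pct / 100) + 1) / 2
}

#' Ground-truth motion velocity field for one phase
#'
#' Analytic stationary velocity field: a superior-inferior component
#' `a(phase) * A * w(x)` with `a(50%) = 0` and `a(0%) = 1`, where the
#' spatial weight `w` is 1 in a plateau below the diaphragm plane, decays
#' smoothly to zero toward the lung apex and the body boundary, and ramps
#' off at the inferior face; plus small seeded lateral components (at most
#' 0.2 A). The field is Gaussian band-limited so its integral is
#' near-diffeomorphic.
#'
#' @param cfg a [phantom_config()].
#' @param phase phase percentage in `cfg$phases`.
#' @return A [velocity_field()] (ground truth, voxel units).
#' @export
make_motion <- function(cfg, phase) {
  stopifnot(inherits(cfg, "mr4dct_phantom_config"))
  assert_that(phase %in% cfg$phases, "phase not in cfg$phases")
  shp <- cfg$grid$shape
  a <- phase_amplitude(phase)
  if (a == 0 || cfg$amplitude == 0) {
    return(velocity_field(array(0, c(shp, 3)), cfg$grid))
  }
  nc <- norm_coords(shp)
  # plateau below the diaphragm (z ~ 0.70), fade to 0 at the apex (0.97),
  # ramp off toward the inferior face, fade at the lateral body boundary
  wz <- (1 - smoothstep(nc$z, 0.70, 0.97)) * smoothstep(nc$z, 0.02, 0.26)
  rho <- ((nc$x - 0.5) / 0.42)^2 + ((nc$y - 0.5) / 0.38)^2
  wxy <- 1 - smoothstep(rho, 0.8, 1.15)
  w <- wz * wxy
  amp_vox_z <- cfg$amplitude / cfg$grid$spacing[3]
  u <- array(0, c(shp, 3))
  u[, , , 3] <- a * amp_vox_z * w
  # lateral components model coherent bulk organ drift: the correlation
  # length (sigma = 8 voxels) is kept well above the smallest organ so label
  # transport stays interpolation-limited rather than rounding-limited
  lat <- with_seed(derive_seed(cfg$seed, 23), {
    lapply(1:2, function(c2) {
      n <- cpp_gauss_smooth(array(rnorm(prod(shp)), shp), 8)
      n / max(abs(n))
    })
  })
  for (c2 in 1:2) {
    amp_vox <- 0.2 * cfg$amplitude / cfg$grid$spacing[c2]
    u[, , , c2] <- a * amp_vox * lat[[c2]] * w
  }
  for (c2 in 1:3) {
    u[, , , c2] <- cpp_gauss_smooth(u[, , , c2, drop = TRUE], 1)
  }
  velocity_field(u, cfg$grid)
}

#' Generate the companion MR-like volume
#'
#' Applies the per-organ MR contrast table (not a monotone remap of the CT
#' intensities), a smooth multiplicative bias field, additive noise, the
#' ground-truth rigid misalignment, and the field-of-view crop along z. The
#' result is a multi-modal registration problem with known ground truth.
#'
#' @param cfg a [phantom_config()].
#' @param ct50 reference anatomy volume from [make_anatomy()].
#' @param labels reference label map from [make_anatomy()].
#' @return List with `mr` (a [volume()] on its native cropped grid),
#'   `labels_mr` (a [label_map()] on the same grid), and `aligned_labels`
#'   (the uncropped misaligned label map on the CT grid, used to derive
#'   field-of-view flags).
#' @export
make_mr <- function(cfg, ct50, labels) {
  stopifnot(inherits(cfg, "mr4dct_phantom_config"))
  g <- cfg$grid
  shp <- g$shape
  organs <- phantom_organs()
  organs <- organs[organs$name %in% cfg$organs, ]
  mr <- array(0, shp)
  for (i in seq_len(nrow(organs))) {
    mr[labels$data == organs$organ_id[i]] <- organs$mr[i]
  }
  mr <- with_seed(derive_seed(cfg$seed, 37), {
    bias_raw <- cpp_gauss_smooth(array(rnorm(prod(shp)), shp), 8)
    bias <- 1 + 0.15 * bias_raw / max(abs(bias_raw))
    noise <- array(rnorm(prod(shp), sd = 0.03), shp)
    pmax(mr * bias + noise * (labels$data > 0), 0)
  })
  # misalign: sample through the inverse map so that rigid_align recovers
  # cfg$mr_misalignment
  inv <- rigid_inverse_field(cfg$mr_misalignment, g)
  mr_mis <- cpp_warp_linear(array(mr, c(shp, 1L)), inv$u, 0L)
  lab_mis <- cpp_warp_nearest(array(labels$data + 0.0, c(shp, 1L)), inv$u)
  lab_mis <- array(as.integer(round(lab_mis)), shp)
  # crop the z extent to the MR field of view
  nkeep <- max(1L, round(cfg$mr_fov_crop * shp[3]))
  zc <- round(0.52 * shp[3])
  z0 <- min(max(1L, zc - nkeep %/% 2L), shp[3] - nkeep + 1L)
  zidx <- z0:(z0 + nkeep - 1L)
  mr_grid <- grid3(c(shp[1:2], nkeep), g$spacing,
                   c(g$origin[1:2], g$origin[3] + (z0 - 1) * g$spacing[3]))
  mr_vol <- volume(array(mr_mis, shp)[, , zidx, drop = FALSE], mr_grid, "MR")
  labels_mr <- label_map(lab_mis[, , zidx, drop = FALSE], mr_grid,
                         labels$registry)
  if (all(labels_mr$data == 0L) ||
      !any(labels_mr$registry$supervised &
             labels_mr$registry$organ_id %in% labels_mr$data)) {
    abort("MR field-of-view crop removed all supervised organs")
  }
  list(mr = mr_vol, labels_mr = labels_mr,
       aligned_labels = label_map(lab_mis, g, labels$registry))
}

#' Assemble a full synthetic study
#'
#' CT phase volumes are the reference anatomy warped by the integrated
#' ground-truth motion fields (labels warped by the same fields with
#' nearest-neighbour interpolation); the MR-like volume comes from
#' [make_mr()]. With probability `artifact_rate` a phase receives a
#' duplicated, shifted axial slab emulating an irregular-breathing binning
#' artifact. All ground truth (per-phase velocity and displacement fields,
#' the rigid misalignment, the diaphragm-apex landmark) is retained.
#'
#' @param cfg a [phantom_config()].
#' @return A list of class `mr4dct_study`; see Details.
#' @details The returned study contains `grid` (native CT grid), `phases`,
#'   `ct` and `labels_ct` (named lists by phase), `mr` and `labels_mr`
#'   (native MR grid), `registry` (with `full_fov` flags reflecting the MR
#'   coverage), `truth` (`svf`, `ddf`, `rigid`), `landmark` (1-based voxel
#'   index of the diaphragm apex), and `config`.
#' @export
make_study <- function(cfg) {
  anat <- make_anatomy(cfg)
  base <- anat$ct50
  labels <- anat$labels
  g <- cfg$grid
  mrp <- make_mr(cfg, base, labels)

  # field-of-view flags: organ fully inside the MR FoV iff the crop kept
  # every one of its (misaligned-frame) voxels
  registry <- labels$registry
  full_counts <- table(factor(mrp$aligned_labels$data,
                              levels = registry$organ_id))
  crop_counts <- table(factor(mrp$labels_mr$data, levels = registry$organ_id))
  registry$full_fov <- as.integer(crop_counts) == as.integer(full_counts) &
    as.integer(full_counts) > 0
  labels$registry <- registry
  mrp$labels_mr$registry <- registry

  phases <- cfg$phases
  keys <- as.character(phases)
  svf <- ddf <- ct <- labels_ct <- setNames(vector("list", length(phases)),
                                            keys)
  art_draw <- with_seed(derive_seed(cfg$seed, 53), {
    list(u = runif(length(phases)),
         z = sample.int(max(1L, g$shape[3] - 6L), length(phases),
                        replace = TRUE),
         s = sample(1:2, length(phases), replace = TRUE))
  })
  for (i in seq_along(phases)) {
    ph <- phases[i]
    v <- make_motion(cfg, ph)
    phi <- integrate_svf(v)
    phi <- displacement_field(phi$u, g, "ground-truth")
    svf[[i]] <- v
    ddf[[i]] <- phi
    if (ph == 50) {
      ct[[i]] <- base
      labels_ct[[i]] <- labels
    } else {
      vol <- warp(base, phi, "trilinear")
      # zero-fill enters from outside the body; treat it as air
      vol$data[vol$data == 0 & base$data <= -900] <- -1000
      vol$phase <- ph
      lm <- warp(labels, phi, "nearest")
      if (cfg$artifact_rate > 0 && art_draw$u[i] < cfg$artifact_rate) {
        z0 <- art_draw$z[i]
        sh <- art_draw$s[i]
        zs <- z0:min(z0 + 2L, g$shape[3])
        vol$data[, , zs] <- vol$data[, , pmax(zs - sh, 1L)]
        lm$data[, , zs] <- lm$data[, , pmax(zs - sh, 1L)]
      }
      ct[[i]] <- vol
      labels_ct[[i]] <- lm
    }
  }

  # diaphragm apex: topmost liver voxel at the liver center column
  liver_id <- registry$organ_id[registry$name == "liver"]
  landmark <- NULL
  if (length(liver_id) == 1 && any(labels$data == liver_id)) {
    ijk <- which(labels$data == liver_id, arr.ind = TRUE)
    top <- max(ijk[, 3])
    atop <- ijk[ijk[, 3] == top, , drop = FALSE]
    landmark <- as.integer(atop[ceiling(nrow(atop) / 2), ])
  }

  structure(list(grid = g, phases = phases, ct = ct, labels_ct = labels_ct,
                 mr = mrp$mr, labels_mr = mrp$labels_mr,
                 registry = registry,
                 truth = list(svf = svf, ddf = ddf,
                              rigid = cfg$mr_misalignment),
                 landmark = landmark, config = cfg),
            class = "mr4dct_study")
}

#' @export
print.mr4dct_study <- function(x, ...) {
  cat(sprintf("<4D study: %d phases on %s, MR FoV %s, A = %g mm>\n",
              length(x$phases), paste(x$grid$shape, collapse = "x"),
              paste(x$mr$grid$shape, collapse = "x"),
              x$config$amplitude))
  invisible(x)
}

#' Generate a cohort of phantom studies
#'
#' @param n number of subjects.
#' @param cfg a [phantom_config()] template; each subject gets a derived
#'   seed.
#' @param seed cohort seed.
#' @return A named list (`subj01`, ...) of [make_study()] results.
#' @export
phantom_cohort <- function(n, cfg = phantom_config(), seed = 0L) {
  out <- lapply(seq_len(n), function(i) {
    ci <- cfg
    ci$seed <- derive_seed(seed, 100 + i)
    make_study(ci)
  })
  names(out) <- sprintf("subj%02d", seq_len(n))
  out
}
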