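#' Stationary velocity field
#'
#' A dense, time-constant velocity with one 3-vector per voxel, in voxel
#' units. Its flow (group exponential), computed by scaling-and-squaring,
#' yields a near-diffeomorphic displacement field. Velocity and displacement
#' fields are kept in voxel units internally; conversion to mm happens only
#' at NIfTI export.
#'
#' @param u 4D array `(X, Y, Z, 3)` of voxel-unit velocities, finite.
#' @param grid a [grid3()].
#' @return An object of class `mr4dct_velocity`.
#' @export
velocity_field <- function(u, grid) {
  u <- as.array(u)
  assert_that(length(dim(u)) == 4 && dim(u)[4] == 3 &&
                all(dim(u)[1:3] == grid$shape),
              "velocity array must be (X,Y,Z,3) matching the grid")
  assert_that(all(is.finite(u)), "velocity field must be finite")
  storage.mode(u) <- "double"
  structure(list(u = u, grid = grid), class = "mr4dct_velocity")
}

#' Dense displacement field
#'
#' Defines the deformation `phi(x) = x + u(x)` (voxel units). Images are
#' warped by *pulling*: `warped(x) = image(phi(x))`.
#'
#' @param u 4D array `(X, Y, Z, 3)` of voxel-unit displacements, finite.
#' @param grid a [grid3()].
#' @param provenance one of `"integrated"`, `"composed"`, `"rigid"`,
#'   `"upsampled"`, `"ground-truth"`.
#' @return An object of class `mr4dct_field`.
#' @export
displacement_field <- function(u, grid,
                               provenance = c("integrated", "composed",
                                              "rigid", "upsampled",
                                              "ground-truth")) {
  provenance <- match.arg(provenance)
  u <- as.array(u)
  assert_that(length(dim(u)) == 4 && dim(u)[4] == 3 &&
                all(dim(u)[1:3] == grid$shape),
              "displacement array must be (X,Y,Z,3) matching the grid")
  assert_that(all(is.finite(u)), "displacement field must be finite")
  storage.mode(u) <- "double"
  structure(list(u = u, grid = grid, provenance = provenance),
            class = "mr4dct_field")
}

zero_field <- function(grid, provenance = "rigid") {
  displacement_field(array(0, c(grid$shape, 3)), grid, provenance)
}

#' @export
print.mr4dct_velocity <- function(x, ...) {
  cat(sprintf("<velocity field %s, max |u| = %.3f voxels>\n",
              paste(dim(x$u)[1:3], collapse = "x"), max(abs(x$u))))
  invisible(x)
}

#' @export
print.mr4dct_field <- function(x, ...) {
  cat(sprintf("<displacement field %s (%s), max |u| = %.3f voxels>\n",
              paste(dim(x$u)[1:3], collapse = "x"), x$provenance,
              max(abs(x$u))))
  invisible(x)
}

#' Integrate a stationary velocity field by scaling and squaring
#'
#' The velocity is scaled by `2^-steps` and the resulting small displacement
#' is self-composed `steps` times, approximating the group exponential of
#' the flow. Seven steps is the working default. Sample coordinates during
#' self-composition are clamped to the grid border, which keeps the
#' recursion stable at the volume faces.
#'
#' @param v a [velocity_field()].
#' @param steps number of squaring steps (>= 1).
#' @return A [displacement_field()] with provenance `"integrated"`.
#' @export
integrate_svf <- function(v, steps = 7L) {
  stopifnot(inherits(v, "mr4dct_velocity"))
  assert_that(steps >= 1, "steps must be >= 1")
  u <- integrate_svf_fwd(v$u, steps)$u
  displacement_field(u, v$grid, "integrated")
}

# forward with cache for backprop: returns final u and all intermediates
integrate_svf_fwd <- function(varr, steps) {
  u <- varr / 2^steps
  cache <- vector("list", steps)
  for (k in seq_len(steps)) {
    cache[[k]] <- u
    u <- u + cpp_warp_linear(u, u, 1L)
  }
  list(u = u, cache = cache)
}

# backward: gradient of loss wrt the (unscaled) velocity array
integrate_svf_bwd <- function(cache, g, steps) {
  for (k in rev(seq_len(steps))) {
    u_prev <- cache[[k]]
    bw <- cpp_warp_linear_bwd(u_prev, u_prev, g, 1L)
    g <- g + bw$gsrc + bw$gdisp
  }
  g / 2^steps
}

#' Warp an image or label map with a displacement field
#'
#' Spatial-transformer sampling: `out(x) = input(x + u(x))`. Samples falling
#' outside the input grid return 0 (background). Label maps require
#' nearest-neighbour interpolation.
#'
#' @param v a [volume()], [label_map()], [binary_mask()] or plain 3D/4D
#'   array.
#' @param phi a [displacement_field()] on the same grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return Same class as `v`, warped.
#' @export
warp <- function(v, phi, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(phi, "mr4dct_field"))
  if (inherits(v, "mr4dct_labelmap")) {
    assert_that(interpolation == "nearest",
                "label maps must be warped with nearest interpolation")
    assert_that(same_grid(v$grid, phi$grid), "grid mismatch in warp")
    out <- cpp_warp_nearest(array(v$data + 0.0, c(dim(v$data), 1L)), phi$u)
    return(label_map(array(as.integer(round(out)), dim(v$data)), v$grid,
                     v$registry))
  }
  if (inherits(v, "mr4dct_mask")) {
    assert_that(same_grid(v$grid, phi$grid), "grid mismatch in warp")
    out <- cpp_warp_nearest(array(v$data + 0.0, c(dim(v$data), 1L)), phi$u)
    return(binary_mask(array(out > 0.5, dim(v$data)), v$grid))
  }
  if (inherits(v, "mr4dct_volume")) {
    assert_that(same_grid(v$grid, phi$grid), "grid mismatch in warp")
    arr <- array(v$data, c(dim(v$data), 1L))
    out <- if (interpolation == "nearest") {
      cpp_warp_nearest(arr, phi$u)
    } else {
      cpp_warp_linear(arr, phi$u, 0L)
    }
    return(volume(array(out, dim(v$data)), v$grid, v$modality, v$phase))
  }
  # plain array (3D or 4D multi-channel)
  arr <- as.array(v)
  if (length(dim(arr)) == 3) arr <- array(arr, c(dim(arr), 1L))
  out <- if (interpolation == "nearest") {
    cpp_warp_nearest(arr, phi$u)
  } else {
    cpp_warp_linear(arr, phi$u, 0L)
  }
  if (length(dim(v)) == 3) array(out, dim(v)) else out
}

#' Compose two displacement fields
#'
#' `compose(phi_then, phi_after)` returns the field equivalent to warping
#' first with `phi_then` and then with `phi_after`:
#' `u(x) = u_after(x) + u_then(x + u_after(x))`, with `u_then` sampled
#' trilinearly (border-clamped). Warping once with the composition
#' approximates sequential warping up to a single extra interpolation.
#'
#' @param phi_then,phi_after [displacement_field()]s on the same grid.
#' @return A [displacement_field()] with provenance `"composed"`.
#' @export
compose_fields <- function(phi_then, phi_after) {
  stopifnot(inherits(phi_then, "mr4dct_field"),
            inherits(phi_after, "mr4dct_field"))
  assert_that(same_grid(phi_then$grid, phi_after$grid),
              "compose requires fields on the same grid")
  u <- phi_after$u + cpp_warp_linear(phi_then$u, phi_after$u, 1L)
  displacement_field(u, phi_then$grid, "composed")
}

#' Upsample a displacement field to a finer grid
#'
#' Each component is interpolated trilinearly onto the target grid (the 3D
#' reading of "bilinear" upsampling) and rescaled from source to target
#' voxel units so the physical displacement in mm is preserved. The target
#' grid must cover the same physical extent within half a coarse voxel.
#'
#' @param phi a [displacement_field()].
#' @param target a [grid3()] refining the same extent.
#' @return A [displacement_field()] with provenance `"upsampled"`.
#' @export
upsample_field <- function(phi, target) {
  stopifnot(inherits(phi, "mr4dct_field"))
  if (same_grid(phi$grid, target)) {
    return(displacement_field(phi$u, target, "upsampled"))
  }
  es <- grid_extent(phi$grid)
  et <- grid_extent(target)
  tol <- max(phi$grid$spacing) / 2 + 1e-9
  assert_that(max(abs(es - et)) <= tol,
              "target grid does not cover the same physical extent")
  out <- array(0, c(target$shape, 3))
  for (c in 1:3) {
    # border-clamped sampling: the fine grid's outermost voxel centers sit
    # half a coarse voxel beyond the coarse centers; zero-filling there
    # would shear the field at the volume faces
    comp <- resample_array(phi$u[, , , c, drop = TRUE], phi$grid, target,
                           clamp = TRUE)
    out[, , , c] <- comp * phi$grid$spacing[c] / target$spacing[c]
  }
  displacement_field(out, target, "upsampled")
}

# 3x3 Jacobian components of phi(x) = x + u(x), voxel units; central
# differences with one-sided stencils at faces. Returns list J[[i]][[j]].
jacobian_components <- function(u) {
  J <- vector("list", 3)
  for (i in 1:3) {
    J[[i]] <- vector("list", 3)
    ui <- u[, , , i, drop = TRUE]
    for (j in 1:3) {
      d <- axis_cdiff(ui, j)
      if (i == j) d <- d + 1
      J[[i]][[j]] <- d
    }
  }
  J
}

jacobian_det <- function(u) {
  J <- jacobian_components(u)
  J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
}

#' Jacobian-determinant deformation-QA report
#'
#' Computes the per-voxel determinant of the Jacobian of `phi(x) = x + u(x)`
#' (central differences, one-sided at volume faces), the folding fraction
#' (voxels with determinant <= 0 — determinant exactly 0 is degenerate and
#' counted as folded), and the standard deviation of the log determinant
#' over voxels with determinant > 1e-6. When a mask is given, masked
#' variants restrict both statistics to mask voxels.
#'
#' @param phi a [displacement_field()].
#' @param mask optional [binary_mask()] on the same grid.
#' @return An object of class `mr4dct_jacobian`: list with `det` (array),
#'   `foldings_fraction`, `std_log_jacobian` and, if masked,
#'   `foldings_fraction_mask`, `std_log_jacobian_mask`.
#' @export
jacobian_report <- function(phi, mask = NULL) {
  stopifnot(inherits(phi, "mr4dct_field"))
  det <- jacobian_det(phi$u)
  eps <- 1e-6
  stdlj <- function(d) {
    pos <- d[d > eps]
    if (length(pos) < 2) return(0)
    sd(log(pos))
  }
  out <- list(det = det,
              foldings_fraction = mean(det <= 0),
              std_log_jacobian = stdlj(det))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mr4dct_mask"))
    assert_that(same_grid(mask$grid, phi$grid), "mask grid mismatch")
    dm <- det[mask$data]
    out$foldings_fraction_mask <- if (length(dm)) mean(dm <= 0) else NA_real_
    out$std_log_jacobian_mask <- stdlj(dm)
  }
  structure(out, class = "mr4dct_jacobian")
}

#' @export
print.mr4dct_jacobian <- function(x, ...) {
  cat(sprintf("<jacobian report: foldings %.4f%%, StdLJ %.4f>\n",
              100 * x$foldings_fraction, x$std_log_jacobian))
  invisible(x)
}
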