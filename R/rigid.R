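#' Rigid transformation parameters
#'
#' Translation in mm and rotation in radians (axis-angle about the grid
#' axes, composed as `Rz %*% Ry %*% Rx`, applied about the volume physical
#' center — the center minimizes translation-rotation coupling during
#' optimization).
#'
#' @param translation numeric length-3, mm.
#' @param rotation numeric length-3, radians in `(-pi, pi]`.
#' @return A list of class `mr4dct_rigid`.
#' @export
rigid_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  assert_that(is_number3(translation), "translation must be three numbers")
  assert_that(is_number3(rotation) && all(rotation > -pi) &&
                all(rotation <= pi),
              "rotations must be in (-pi, pi]")
  structure(list(translation = as.double(translation),
                 rotation = as.double(rotation)),
            class = "mr4dct_rigid")
}

#' @export
print.mr4dct_rigid <- function(x, ...) {
  cat(sprintf("<rigid: t = (%s) mm, r = (%s) rad>\n",
              paste(sprintf("%.2f", x$translation), collapse = ", "),
              paste(sprintf("%.4f", x$rotation), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# dense field for the map T(x) = R (x - c) + c + t (physical mm), returned
# in voxel units on `grid`; u(x) = T(x) - x
rigid_field_from_matrix <- function(R, t, grid) {
  shp <- grid$shape
  cx <- grid_center(grid)
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(shp[a]) - 1) * grid$spacing[a]
  })
  u <- array(0, c(shp, 3))
  # T(x) - x = (R - I)(x - c) + t
  A <- R - diag(3)
  X1 <- ax[[1]] - cx[1]
  X2 <- ax[[2]] - cx[2]
  X3 <- ax[[3]] - cx[3]
  for (i in 1:3) {
    comp <- A[i, 1] * array(X1, shp) +
      A[i, 2] * aperm(array(X2, shp[c(2, 1, 3)]), c(2, 1, 3)) +
      A[i, 3] * aperm(array(X3, shp[c(3, 1, 2)]), c(2, 3, 1)) + t[i]
    u[, , , i] <- comp / grid$spacing[i]
  }
  u
}

#' Dense displacement field of a rigid transform
#'
#' Exact voxelwise representation of the rigid map on a grid, so rigid and
#' deformable transforms compose uniformly through [compose_fields()].
#'
#' @param p a [rigid_params()].
#' @param grid a [grid3()].
#' @return A [displacement_field()] with provenance `"rigid"`.
#' @export
rigid_to_field <- function(p, grid) {
  stopifnot(inherits(p, "mr4dct_rigid"))
  u <- rigid_field_from_matrix(rotation_matrix(p$rotation), p$translation,
                               grid)
  displacement_field(u, grid, "rigid")
}

# inverse of the rigid map: T^-1 has rotation R^-1 and translation -R^-1 t
rigid_inverse_field <- function(p, grid) {
  R <- rotation_matrix(p$rotation)
  Ri <- t(R)
  u <- rigid_field_from_matrix(Ri, -as.vector(Ri %*% p$translation), grid)
  displacement_field(u, grid, "rigid")
}

# fast plain-histogram MI (not the differentiable Parzen estimator) used as
# the rigid objective; both images in [0, 1]
histogram_mi <- function(f, m, bins = 48L, mask = NULL) {
  idx <- if (is.null(mask)) seq_along(f) else which(mask)
  fi <- pmin(pmax(floor(f[idx] * bins), 0), bins - 1)
  mi_ <- pmin(pmax(floor(m[idx] * bins), 0), bins - 1)
  joint <- tabulate(fi * bins + mi_ + 1, nbins = bins * bins)
  P <- matrix(joint / length(idx), bins, bins, byrow = TRUE)
  pf <- rowSums(P)
  pm <- colSums(P)
  nz <- P > 0
  sum(P[nz] * (log(P[nz]) - log(outer(pf, pm)[nz])))
}

#' Rigid pre-alignment of MR to the reference-phase CT
#'
#' Multi-resolution (3-level) derivative-free optimization of mutual
#' information over the 6 rigid degrees of freedom, starting from the
#' identity with a few seeded coarse-level restarts. Returns the recovered
#' parameters, the equivalent dense displacement field on the CT grid, and
#' the overlap region: the MR support mask transported by the recovered
#' rigid map.
#'
#' @param mr MR [volume()] already resampled/zero-padded onto the CT grid,
#'   intensities in `[0, 1]`.
#' @param ct50 reference-phase CT [volume()], intensities in `[0, 1]`.
#' @param seed integer seed for the restart jitter.
#' @param support optional [binary_mask()]: the native MR field-of-view
#'   support on the CT grid (defaults to all-true).
#' @param bins histogram bins for the MI objective.
#' @param restarts number of additional best grid cells refined by
#'   Nelder-Mead (beyond the best one).
#' @param maxit Nelder-Mead iterations per pyramid level.
#' @param grid_search_span list of three mm-offset vectors defining the
#'   coarse-level translation search grid.
#' @return A list of class `mr4dct_rigid_result`: `params`, `field`,
#'   `omega`, `improved` (FALSE when optimization failed to beat the
#'   identity, in which case identity parameters are returned with a
#'   warning), `mi_identity`, `mi_final`.
#' @export
rigid_align <- function(mr, ct50, seed = 0L, support = NULL, bins = 48L,
                        restarts = 2L, maxit = 150L,
                        grid_search_span = rep(list(seq(-12, 12, 4)), 3)) {
  stopifnot(inherits(mr, "mr4dct_volume"), inherits(ct50, "mr4dct_volume"))
  assert_that(same_grid(mr$grid, ct50$grid),
              "mr must be resampled to the ct50 grid first")
  g <- ct50$grid
  support <- support %||% binary_mask(array(TRUE, g$shape), g)

  pyramid <- list()
  for (f in c(4, 2, 1)) {
    if (any(g$shape < 2 * f)) next
    gl <- grid3(pmax(g$shape %/% f, 1L), g$spacing * f, g$origin)
    pyramid[[length(pyramid) + 1]] <- list(
      ct = resample_array(ct50$data, g, gl),
      mr = resample_array(mr$data, g, gl),
      sup = resample_array(support$data + 0.0, g, gl, nearest = TRUE),
      grid = gl,
      bins = max(8L, bins %/% f))
  }

  objective <- function(theta, lev) {
    p <- rigid_params(theta[1:3], clamp_rot(theta[4:6]))
    fld <- rigid_to_field(p, lev$grid)
    dm <- c(dim(lev$mr), 1L)
    warped <- cpp_warp_linear(array(lev$mr, dm), fld$u, 0L)
    # MI over the *transported* MR support: evaluating over warped-intensity
    # voxels instead creates a zero-padding artifact that corrupts the
    # objective away from integer-voxel shifts
    msk <- cpp_warp_nearest(array(lev$sup, dm), fld$u) > 0.5
    if (sum(msk) < 64) return(0)
    -histogram_mi(lev$ct, warped, lev$bins, mask = msk)
  }

  # coarse-level exhaustive translation grid, then Nelder-Mead refinement
  # from the few best cells: local search alone is prone to false MI optima
  # (periodic-looking anatomy along z), the grid restart escapes them
  lev1 <- pyramid[[1]]
  span <- grid_search_span
  cand <- as.matrix(expand.grid(x = span[[1]], y = span[[2]],
                                z = span[[3]]))
  scores <- apply(cand, 1, function(t3) {
    objective(c(t3, 0, 0, 0), lev1)
  })
  top <- order(scores)[seq_len(min(max(1L, restarts + 1L), nrow(cand)))]
  jitter_rot <- with_seed(derive_seed(seed, 1), {
    lapply(seq_along(top), function(i) runif(3, -0.02, 0.02))
  })
  theta <- numeric(6)
  best <- Inf
  for (i in seq_along(top)) {
    s <- c(cand[top[i], ], if (i == 1) c(0, 0, 0) else jitter_rot[[i]])
    o <- stats::optim(s, objective, lev = lev1, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(rep(2, 3), rep(0.02, 3))))
    if (o$value < best) {
      best <- o$value
      theta <- o$par
    }
  }
  for (lev in pyramid[-1]) {
    o <- stats::optim(theta, objective, lev = lev, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(rep(2, 3), rep(0.02, 3))))
    if (o$value <= objective(theta, lev)) theta <- o$par
  }

  lev_f <- pyramid[[length(pyramid)]]
  mi_id <- -objective(numeric(6), lev_f)
  mi_fin <- -objective(theta, lev_f)
  improved <- mi_fin >= mi_id
  if (!improved) {
    warn("rigid optimization did not improve on the identity; returning identity")
    theta <- numeric(6)
  }
  params <- rigid_params(theta[1:3], clamp_rot(theta[4:6]))
  fld <- rigid_to_field(params, g)
  omega <- warp(support, fld, "nearest")
  structure(list(params = params, field = fld, omega = omega,
                 improved = improved, mi_identity = mi_id,
                 mi_final = max(mi_fin, mi_id)),
            class = "mr4dct_rigid_result")
}

clamp_rot <- function(r) {
  ((r + pi) %% (2 * pi)) - pi
}

#' @export
print.mr4dct_rigid_result <- function(x, ...) {
  cat(sprintf("<rigid alignment: MI %.4f -> %.4f%s>\n", x$mi_identity,
              x$mi_final, if (x$improved) "" else " (identity fallback)"))
  print(x$params)
  invisible(x)
}
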