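#' Regular 3D sampling grid
#'
#' A grid couples an array shape to physical space: voxel `(i, j, k)`
#' (0-based) has its *center* at `origin + c(i, j, k) * spacing` (mm). The
#' physical extent of the grid is the box covering all voxel centers plus
#' half a spacing on every side. Only axis-aligned grids are supported.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, mm position of the center of
#'   voxel (0,0,0).
#' @return An object of class `mr4dct_grid`.
#' @examples
#' g <- grid3(c(48, 48, 32), c(2, 2, 2))
#' grid_extent(g)
#' @export
grid3 <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape >= 1L),
              "grid shape must be three integers >= 1")
  assert_that(is_number3(spacing) && all(spacing > 0),
              "grid spacing must be three positive numbers")
  assert_that(is_number3(origin), "grid origin must be three finite numbers")
  structure(list(shape = shape, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "mr4dct_grid")
}

#' @export
print.mr4dct_grid <- function(x, ...) {
  cat(sprintf("<grid %s @ %s mm, origin (%s)>\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ","),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Physical extent of a grid
#'
#' @param g a [grid3()] object.
#' @return A 2x3 matrix: first row the lower mm bound per axis, second row
#'   the upper bound (voxel centers plus/minus half a spacing).
#' @export
grid_extent <- function(g) {
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$shape - 1 + 0.5) * g$spacing
  rbind(lower = lo, upper = hi)
}

grid_center <- function(g) {
  g$origin + (g$shape - 1) / 2 * g$spacing
}

#' Scalar image volume on a grid
#'
#' @param data 3D numeric array matching `grid$shape`; all values finite.
#' @param grid a [grid3()] object.
#' @param modality `"CT"` or `"MR"`.
#' @param phase optional respiratory phase percentage (CT only).
#' @return An object of class `mr4dct_volume`.
#' @export
volume <- function(data, grid, modality = c("CT", "MR"), phase = NULL) {
  modality <- match.arg(modality)
  data <- as.array(data)
  assert_that(length(dim(data)) == 3 && all(dim(data) == grid$shape),
              "volume data dimensions must equal grid shape")
  assert_that(all(is.finite(data)), "volume data must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, grid = grid, modality = modality,
                 phase = phase),
            class = "mr4dct_volume")
}

#' @export
print.mr4dct_volume <- function(x, ...) {
  ph <- if (is.null(x$phase)) "" else sprintf(" phase %s%%", x$phase)
  cat(sprintf("<%s volume %s%s, range [%.3g, %.3g]>\n", x$modality,
              paste(dim(x$data), collapse = "x"), ph,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Organ registry for a label map
#'
#' @param organ_id integer organ ids (> 0).
#' @param name organ names.
#' @param supervised logical; is the organ used for Dice supervision?
#' @param full_fov logical; is the organ fully inside the MR field of view?
#' @return A tibble with one row per organ.
#' @export
organ_registry <- function(organ_id, name, supervised = FALSE,
                           full_fov = TRUE) {
  tibble::tibble(organ_id = as.integer(organ_id), name = as.character(name),
                 supervised = rep_len(supervised, length(organ_id)),
                 full_fov = rep_len(full_fov, length(organ_id)))
}

#' Integer organ segmentation on a grid
#'
#' Voxel value 0 is background; every non-zero value must appear in the
#' registry. Supervised organs (used in the weak Dice loss) are a subset of
#' the registry, flagged in its `supervised` column.
#'
#' @param data 3D integer array matching `grid$shape`, values >= 0.
#' @param grid a [grid3()] object.
#' @param registry an [organ_registry()] tibble.
#' @return An object of class `mr4dct_labelmap`.
#' @export
label_map <- function(data, grid, registry) {
  data <- as.array(data)
  assert_that(length(dim(data)) == 3 && all(dim(data) == grid$shape),
              "label data dimensions must equal grid shape")
  storage.mode(data) <- "integer"
  assert_that(all(data >= 0L), "label values must be non-negative")
  present <- setdiff(unique(as.vector(data)), 0L)
  assert_that(all(present %in% registry$organ_id),
              "every non-zero label value must appear in the registry")
  structure(list(data = data, grid = grid, registry = registry),
            class = "mr4dct_labelmap")
}

#' @export
print.mr4dct_labelmap <- function(x, ...) {
  cat(sprintf("<label map %s, %d organs (%d supervised)>\n",
              paste(dim(x$data), collapse = "x"), nrow(x$registry),
              sum(x$registry$supervised)))
  invisible(x)
}

#' Binary voxel mask on a grid
#'
#' @param data 3D logical (or 0/1) array matching `grid$shape`.
#' @param grid a [grid3()] object.
#' @return An object of class `mr4dct_mask`.
#' @export
binary_mask <- function(data, grid) {
  data <- as.array(data)
  assert_that(length(dim(data)) == 3 && all(dim(data) == grid$shape),
              "mask dimensions must equal grid shape")
  storage.mode(data) <- "logical"
  structure(list(data = data, grid = grid), class = "mr4dct_mask")
}

#' @export
print.mr4dct_mask <- function(x, ...) {
  cat(sprintf("<mask %s, %.1f%% true>\n", paste(dim(x$data), collapse = "x"),
              100 * mean(x$data)))
  invisible(x)
}

#' Rescale image intensities to `[0, 1]` for loss computation
#'
#' CT volumes are clamped to a bounded attenuation range (default
#' `[-1000, 1000]` HU-like) and mapped linearly to `[0, 1]`; MR volumes, which
#' have no calibrated scale, are rescaled by their 1st-99th intensity
#' percentiles and clamped. Bounded intensities are required by the
#' histogram-based mutual-information terms.
#'
#' @param v a [volume()].
#' @param ct_range length-2 clamping range for CT input.
#' @return A [volume()] with values in `[0, 1]`.
#' @export
normalize_intensities <- function(v, ct_range = c(-1000, 1000)) {
  stopifnot(inherits(v, "mr4dct_volume"))
  d <- v$data
  if (v$modality == "CT") {
    d <- pmin(pmax(d, ct_range[1]), ct_range[2])
    d <- (d - ct_range[1]) / diff(ct_range)
  } else {
    qs <- quantile(d, c(0.01, 0.99), names = FALSE)
    if (qs[2] <= qs[1]) qs[2] <- qs[1] + 1
    d <- pmin(pmax((d - qs[1]) / (qs[2] - qs[1]), 0), 1)
  }
  volume(d, v$grid, v$modality, v$phase)
}

# one-hot indicator channels for a subset of organs, (X,Y,Z,K) double array
one_hot <- function(lm, organ_ids) {
  d <- dim(lm$data)
  out <- array(0, c(d, length(organ_ids)))
  for (k in seq_along(organ_ids)) {
    out[, , , k] <- as.double(lm$data == organ_ids[k])
  }
  out
}
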