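#' Read a 3D volume from a NIfTI-1 file
#'
#' Grid spacing and origin are taken from the NIfTI affine, which must be
#' axis-aligned with positive scales (oblique or flipped affines are
#' rejected; the pipeline resamples everything onto the reference CT grid and
#' has no need for rotated storage orders).
#'
#' @param path path to a `.nii` / `.nii.gz` file with 3D scalar data.
#' @param modality `"CT"` or `"MR"` tag attached to the volume.
#' @param phase optional respiratory phase percentage.
#' @return A [volume()].
#' @export
read_volume <- function(path, modality = c("CT", "MR"), phase = NULL) {
  modality <- match.arg(modality)
  parsed <- read_nifti_array(path, expect_dims = 3)
  v <- volume(parsed$data, parsed$grid, modality, phase)
  v
}

#' Write a volume (or label map / mask) to NIfTI-1
#'
#' The affine encodes the grid spacing and origin; `read_volume()` after
#' `write_volume()` round-trips data, spacing and origin at stored precision
#' (float64 for volumes, int32 for label maps, uint8 for masks).
#'
#' @param v a [volume()], [label_map()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  UseMethod("write_volume")
}

#' @export
write_volume.mr4dct_volume <- function(v, path) {
  write_nifti_array(v$data, v$grid, path, datatype = "double")
}

#' @export
write_volume.mr4dct_labelmap <- function(v, path) {
  write_nifti_array(v$data, v$grid, path, datatype = "int32")
}

#' @export
write_volume.mr4dct_mask <- function(v, path) {
  write_nifti_array(v$data + 0L, v$grid, path, datatype = "uint8")
}

#' Read a label map from NIfTI-1
#'
#' @param path path to an integer-valued NIfTI file.
#' @param registry an [organ_registry()]; if `NULL` a minimal registry is
#'   built from the label values found in the file.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, registry = NULL) {
  parsed <- read_nifti_array(path, expect_dims = 3)
  ids <- setdiff(sort(unique(as.vector(parsed$data))), 0)
  assert_that(max(abs(parsed$data - round(parsed$data))) < 1e-6,
              "label map file contains non-integer values")
  if (is.null(registry)) {
    registry <- organ_registry(ids, paste0("organ_", ids))
  }
  label_map(round(parsed$data), parsed$grid, registry)
}

#' Write / read a displacement or velocity field as 4D NIfTI
#'
#' Fields are stored with the vector component as the 4th dimension, in mm
#' (voxel-unit displacements are converted using the grid spacing). A JSON
#' sidecar `<path>.json` records provenance and units.
#'
#' @param f a [displacement_field()] or [velocity_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(f, path) {
  u_mm <- f$u
  for (c in 1:3) u_mm[, , , c] <- u_mm[, , , c] * f$grid$spacing[c]
  write_nifti_array(u_mm, f$grid, path, datatype = "double")
  sidecar <- list(units = "mm", component_order = "xyz",
                  provenance = f$provenance %||% "velocity",
                  kind = if (inherits(f, "mr4dct_velocity")) "velocity"
                         else "displacement")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @param kind `"displacement"` or `"velocity"`; overrides the sidecar if
#'   given.
#' @export
read_field <- function(path, kind = NULL) {
  parsed <- read_nifti_array(path, expect_dims = 4)
  assert_that(dim(parsed$data)[4] == 3,
              "field file must have 3 components in the 4th dimension")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  kind <- kind %||% meta$kind %||% "displacement"
  u <- parsed$data
  for (c in 1:3) u[, , , c] <- u[, , , c] / parsed$grid$spacing[c]
  if (identical(kind, "velocity")) {
    velocity_field(u, parsed$grid)
  } else {
    displacement_field(u, parsed$grid,
                       provenance = meta$provenance %||% "integrated")
  }
}

# --- internal NIfTI plumbing ------------------------------------------------

read_nifti_array <- function(path, expect_dims) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data)) # strip niftiImage attributes
  nd <- length(dim(data))
  assert_that(nd == expect_dims,
              sprintf("expected %dD data but %s has %d dimensions",
                      expect_dims, basename(path), nd))
  assert_that(all(is.finite(data)),
              sprintf("%s contains non-finite voxels", basename(path)))
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- rot
  diag(offdiag) <- 0
  assert_that(max(abs(offdiag)) <= 1e-4 * max(abs(diag(rot))),
              "oblique or sheared NIfTI affines are not supported")
  assert_that(all(diag(rot) > 0),
              "axis-flipping NIfTI affines are not supported")
  g <- grid3(dim(data)[1:3], diag(rot), aff[1:3, 4])
  list(data = data, grid = g)
}

write_nifti_array <- function(data, grid, path, datatype = "double") {
  dir <- dirname(path)
  assert_that(dir.exists(dir), sprintf("directory not writable: %s", dir))
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- if (nd == 4) c(grid$spacing, 1) else grid$spacing
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  img <- RNifti::`qform<-`(img, value = aff)
  img <- RNifti::`sform<-`(img, value = aff)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
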