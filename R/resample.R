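#' Resample a volume or label map onto another grid
#'
#' Physical positions are preserved: target voxel centers are mapped into the
#' source grid through both grids' spacing and origin, and sampled with the
#' requested interpolation. Target voxels with no source coverage are filled
#' with zero — this implements zero-padding when the target grid is larger
#' than the source. Label maps must use nearest-neighbour interpolation so no
#' new label ids can be introduced.
#'
#' @param v a [volume()] or [label_map()].
#' @param target a [grid3()] to resample onto.
#' @param interpolation `"trilinear"` (volumes only) or `"nearest"`.
#' @return An object of the same class as `v`, on `target`.
#' @export
resample_to_grid <- function(v, target,
                             interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(v, "mr4dct_labelmap")) {
    assert_that(interpolation == "nearest",
                "label maps must be resampled with nearest interpolation")
    out <- resample_array(v$data + 0.0, v$grid, target, nearest = TRUE)
    return(label_map(round(out), target, v$registry))
  }
  stopifnot(inherits(v, "mr4dct_volume"))
  out <- resample_array(v$data, v$grid, target,
                        nearest = interpolation == "nearest")
  volume(out, target, v$modality, v$phase)
}

#' Support mask of a volume on a target grid
#'
#' True exactly where the target voxel center falls inside the physical
#' extent of the source grid (voxel centers plus half a spacing per side).
#' Used to carry the native MR field of view onto the CT grid; after rigid
#' mapping this becomes the overlap region within which multi-modal
#' similarity and partial-organ metrics are computed.
#'
#' @param v a [volume()] (or anything with a `$grid`).
#' @param target a [grid3()].
#' @return A [binary_mask()] on `target`.
#' @export
support_mask <- function(v, target) {
  ext <- grid_extent(v$grid)
  centers <- lapply(1:3, function(a) {
    target$origin[a] + (seq_len(target$shape[a]) - 1) * target$spacing[a]
  })
  inside <- lapply(1:3, function(a) {
    centers[[a]] >= ext[1, a] & centers[[a]] <= ext[2, a]
  })
  m <- array(FALSE, target$shape)
  if (all(vapply(inside, any, logical(1)))) {
    m[inside[[1]], inside[[2]], inside[[3]]] <- TRUE
  }
  binary_mask(m, target)
}

resample_array <- function(data, src_grid, target, nearest = FALSE,
                           clamp = FALSE) {
  off <- (target$origin - src_grid$origin) / src_grid$spacing
  sc <- target$spacing / src_grid$spacing
  cpp_resample(data, as.integer(target$shape), off, sc,
               as.integer(nearest), as.integer(clamp))
}
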