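# Preprocessing: window leveling, 2x local-mean downscale, and breast-region
# segmentation (erosion for skin removal + largest connected component).
# The step order is fixed: window -> downscale -> mask.

#' Window-level a slice
#'
#' Linear map of `[center - width/2, center + width/2]` onto `[0, 1]`,
#' clipped outside. Monotone nondecreasing in the pixel value.
#'
#' @param slice numeric matrix.
#' @param center,width window parameters (header units); `width > 0`.
#' @return Matrix with values in `[0, 1]`.
#' @export
window_level <- function(slice, center, width) {
  if (width <= 0) stop_dbt("parameter", "window width must be > 0")
  clamp((slice - (center - width / 2)) / width, 0, 1)
}

#' Downscale a slice by 2 with a 2x2 local mean filter
#'
#' `out[i, j]` is the mean of the 2x2 input block at `(2i, 2j)`; a trailing
#' odd row/column is dropped.
#'
#' @param slice numeric matrix.
#' @return Matrix of halved (floored) dimensions.
#' @export
downscale_2x <- function(slice) {
  h2 <- nrow(slice) %/% 2L
  w2 <- ncol(slice) %/% 2L
  if (h2 == 0L || w2 == 0L) return(matrix(numeric(0), h2, w2))
  x <- slice[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  # fold rows then columns via colMeans over a length-2 leading dimension
  rowsum <- matrix(.colMeans(x, 2L, h2 * w2 * 2L), h2, 2L * w2)
  t(matrix(.colMeans(t(rowsum), 2L, w2 * h2), w2, h2))
}

#' Segment the breast region of a preprocessed slice
#'
#' Binary erosion of the nonzero pixels with a discrete disk
#' `{(di, dj): di^2 + dj^2 <= radius^2}` (skin removal), followed by the
#' largest 8-connected component. The result may be empty (all `FALSE`).
#'
#' @param slice window-leveled, downscaled slice.
#' @param radius erosion radius in (downscaled) pixels; default 5.
#' @return Logical matrix aligned with `slice`.
#' @export
breast_mask <- function(slice, radius = 5) {
  nz <- slice > 0
  eroded <- cpp_erode_disk(nz, radius)
  if (!any(eroded)) return(eroded)
  cpp_largest_component8(eroded)
}

#' Preprocess a DBT volume
#'
#' Applies [window_level()] then [downscale_2x()] to every slice and
#' computes a per-slice [breast_mask()] on the result.
#'
#' @param volume a [new_volume()] object (raw intensities).
#' @param radius erosion radius passed to [breast_mask()].
#' @return List with `volume` (the preprocessed `dbt_volume`, intensities
#'   in `[0, 1]`) and `masks` (list of logical matrices, one per slice).
#' @export
preprocess_volume <- function(volume, radius = 5) {
  ns <- n_slices(volume)
  wl <- window_level(volume$pixels, volume$window_center,
                     volume$window_width)
  d2 <- c(dim(wl)[1] %/% 2L, dim(wl)[2] %/% 2L)
  out <- array(0, dim = c(d2[1], d2[2], ns))
  masks <- vector("list", ns)
  for (k in seq_len(ns)) {
    sl <- downscale_2x(wl[, , k])
    out[, , k] <- sl
    masks[[k]] <- breast_mask(sl, radius)
  }
  pp <- new_volume(out, view = volume$view, patient_id = volume$patient_id,
                   study_id = volume$study_id,
                   window_center = volume$window_center,
                   window_width = volume$window_width)
  list(volume = pp, masks = masks)
}
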