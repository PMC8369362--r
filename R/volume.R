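#' DBT reconstruction volume
#'
#' Container for one reconstruction view of a digital breast tomosynthesis
#' (DBT) study: a stack of grayscale slices plus the metadata the pipeline
#' needs (view, identifiers, window-level parameters from the file header).
#'
#' Pixels are stored as a 3-D array indexed `[row, col, slice]` with
#' nonnegative intensities. All box coordinates in this package are 0-based
#' with `x` along columns and `y` along rows, and boxes are half-open
#' `[x, x + width) x [y, y + height)`.
#'
#' @param pixels numeric array `[row, col, slice]`, intensities >= 0.
#' @param view one of `"LCC"`, `"RCC"`, `"LMLO"`, `"RMLO"`.
#' @param patient_id,study_id identifier strings.
#' @param window_center,window_width window-level parameters in header
#'   units; when `NULL` they fall back to `(min + max) / 2` and
#'   `max - min` of the pixel data.
#' @return An object of class `dbt_volume`.
#' @export
new_volume <- function(pixels, view, patient_id = "NA", study_id = "NA",
                       window_center = NULL, window_width = NULL) {
  if (length(dim(pixels)) != 3L)
    stop_dbt("format", "pixels must be a 3-D [row, col, slice] array")
  if (dim(pixels)[3] < 1L) stop_dbt("format", "volume needs at least 1 slice")
  if (any(pixels < 0)) stop_dbt("format", "pixel intensities must be >= 0")
  view <- match.arg(view, c("LCC", "RCC", "LMLO", "RMLO"))
  if (is.null(window_center) || is.null(window_width)) {
    rng <- range(pixels)
    if (is.null(window_center)) window_center <- (rng[1] + rng[2]) / 2
    if (is.null(window_width)) window_width <- max(rng[2] - rng[1], 1)
  }
  structure(
    list(pixels = pixels, view = view, patient_id = patient_id,
         study_id = study_id, window_center = window_center,
         window_width = window_width),
    class = "dbt_volume"
  )
}

#' @export
print.dbt_volume <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<dbt_volume> %s %s/%s: %d x %d px, %d slices, WC=%.5g WW=%.5g\n",
              x$view, x$patient_id, x$study_id, d[1], d[2], d[3],
              x$window_center, x$window_width))
  invisible(x)
}

#' Number of slices in a volume
#' @param volume a `dbt_volume`.
#' @return Integer slice count.
#' @export
n_slices <- function(volume) dim(volume$pixels)[3]

#' Extract one slice as a matrix
#' @param volume a `dbt_volume`.
#' @param z 0-based slice index.
#' @return Numeric matrix `[row, col]`.
#' @export
volume_slice <- function(volume, z) {
  if (z < 0 || z >= n_slices(volume))
    stop_dbt("validation", "slice index out of range: ", z)
  volume$pixels[, , z + 1L]
}
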