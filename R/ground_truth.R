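# Ground-truth construction: the annotated 2-D rectangle on the center
# slice is expanded into a 3-D extent by phase-specific rules, and crops
# are encoded into detector target grids (96 x 96-px cells, one box per
# cell, offsets in cell widths, log scales against a 256 x 256 anchor).

GRID_CELL <- 96L
ANCHOR <- 256

#' Number of positive slices for a lesion
#'
#' The slice extent of a ground-truth box during training:
#' `round(sqrt((width + height) / 2))` (round half to even, as in base R),
#' clamped to at least 1. "Average dimension" is the arithmetic mean of the
#' full-resolution box width and height as drawn by the radiologist.
#'
#' @param width,height box dimensions in full-resolution pixels (> 0).
#' @return Integer >= 1; nondecreasing in both arguments.
#' @export
positive_slice_count <- function(width, height) {
  if (any(width <= 0) || any(height <= 0))
    stop_dbt("parameter", "box dimensions must be positive")
  pmax(1L, as.integer(round(sqrt((width + height) / 2))))
}

#' Slice span of a ground-truth box during training
#'
#' A span of `count` slices centered on the center slice; when `count` is
#' even the extra slice goes below the center. The span is clipped to
#' `[0, n_slices - 1]` without shifting.
#'
#' @param center_slice 0-based center slice.
#' @param count span length (>= 1), e.g. from [positive_slice_count()].
#' @param n_slices number of slices in the volume.
#' @return Integer vector `c(slice_lo, slice_hi)` (inclusive).
#' @export
training_slice_range <- function(center_slice, count, n_slices) {
  if (count < 1) stop_dbt("parameter", "count must be >= 1")
  if (center_slice < 0 || center_slice >= n_slices)
    stop_dbt("validation", "center slice ", center_slice, " outside volume")
  lo <- center_slice - count %/% 2L
  hi <- center_slice + (count - 1L) %/% 2L
  c(max(0L, as.integer(lo)), min(n_slices - 1L, as.integer(hi)))
}

#' Slice span during validation
#'
#' Same as [training_slice_range()] with the count halved
#' (`max(1, round(count / 2))`, round half to even).
#'
#' @inheritParams training_slice_range
#' @return Integer vector `c(slice_lo, slice_hi)`.
#' @export
validation_slice_range <- function(center_slice, count, n_slices) {
  if (count < 1) stop_dbt("parameter", "count must be >= 1")
  training_slice_range(center_slice, max(1L, as.integer(round(count / 2))),
                       n_slices)
}

#' Slice span assumed during evaluation
#'
#' For scoring, a ground-truth box is assumed to span 25% of the volume's
#' slices before and after its center slice:
#' `center +/- round(0.25 * n_slices)`, clipped to the volume.
#'
#' @param center_slice 0-based center slice.
#' @param n_slices number of slices in the volume.
#' @param z_fraction fraction of slices spanned on each side (default 0.25).
#' @return Integer vector `c(slice_lo, slice_hi)`.
#' @export
evaluation_slice_range <- function(center_slice, n_slices,
                                   z_fraction = 0.25) {
  if (center_slice < 0 || center_slice >= n_slices)
    stop_dbt("validation", "center slice outside volume")
  d <- as.integer(round(z_fraction * n_slices))
  c(max(0L, as.integer(center_slice) - d),
    min(n_slices - 1L, as.integer(center_slice) + d))
}

#' Encode boxes into a detector target grid
#'
#' The crop is tiled with 96 x 96-px cells. The cell containing a box
#' center gets objectness 1 and a 4-vector regression target:
#' offsets `(box_center - cell_center) / 96` (in `[-0.5, 0.5)`) and log
#' scales `ln(dim / 256)` against the square anchor. Each cell holds at
#' most one box; on collision the larger-area box wins.
#'
#' @param boxes data.frame with columns `x, y, width, height` in 0-based
#'   crop coordinates (box centers must lie inside the crop).
#' @param crop_shape `c(height, width)` in pixels, multiples of 96.
#' @return A `dbt_target_grid`: list with `objectness` (0/1 matrix,
#'   `height/96` rows x `width/96` cols), `regression`
#'   (rows x cols x 4 array), and `shape`.
#' @export
encode_target_grid <- function(boxes, crop_shape) {
  h <- crop_shape[1]
  w <- crop_shape[2]
  if (h %% GRID_CELL != 0 || w %% GRID_CELL != 0)
    stop_dbt("shape", "crop shape must be a multiple of 96, got ", h, "x", w)
  gr <- h %/% GRID_CELL
  gc <- w %/% GRID_CELL
  obj <- matrix(0, gr, gc)
  reg <- array(0, dim = c(gr, gc, 4))
  if (nrow(boxes) > 0) {
    boxes <- boxes[order(boxes$width * boxes$height), , drop = FALSE]
    for (i in seq_len(nrow(boxes))) {
      cx <- boxes$x[i] + boxes$width[i] / 2
      cy <- boxes$y[i] + boxes$height[i] / 2
      if (cx < 0 || cx >= w || cy < 0 || cy >= h)
        stop_dbt("validation", "box center outside crop")
      cj <- floor(cx / GRID_CELL)
      ci <- floor(cy / GRID_CELL)
      obj[ci + 1, cj + 1] <- 1
      reg[ci + 1, cj + 1, ] <- c(
        (cx - (cj * GRID_CELL + GRID_CELL / 2)) / GRID_CELL,
        (cy - (ci * GRID_CELL + GRID_CELL / 2)) / GRID_CELL,
        log(boxes$width[i] / ANCHOR),
        log(boxes$height[i] / ANCHOR)
      )
    }
  }
  structure(list(objectness = obj, regression = reg, shape = c(h, w)),
            class = "dbt_target_grid")
}

#' Decode a target grid back into boxes
#'
#' Inverse of [encode_target_grid()]; exact (up to float tolerance) for
#' boxes whose centers lie strictly inside the crop.
#'
#' @param grid a `dbt_target_grid`.
#' @return data.frame with columns `x, y, width, height` in crop
#'   coordinates.
#' @export
decode_target_grid <- function(grid) {
  pos <- which(grid$objectness > 0, arr.ind = TRUE)
  if (nrow(pos) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), width = numeric(0),
                      height = numeric(0)))
  out <- lapply(seq_len(nrow(pos)), function(k) {
    ci <- pos[k, 1] - 1
    cj <- pos[k, 2] - 1
    r <- grid$regression[pos[k, 1], pos[k, 2], ]
    cx <- cj * GRID_CELL + GRID_CELL / 2 + GRID_CELL * r[1]
    cy <- ci * GRID_CELL + GRID_CELL / 2 + GRID_CELL * r[2]
    wd <- ANCHOR * exp(r[3])
    ht <- ANCHOR * exp(r[4])
    data.frame(x = cx - wd / 2, y = cy - ht / 2, width = wd, height = ht)
  })
  do.call(rbind, out)
}

#' Expand an annotation into a 3-D ground-truth box
#'
#' Combines the coordinate mapping onto preprocessed images with the
#' phase-specific slice-span rule: the full training span during training,
#' the halved span for validation, and the 25%-of-slices assumption for
#' evaluation.
#'
#' @param annotation one-row data.frame in the [read_annotations()] schema
#'   (full-resolution coordinates).
#' @param n_slices slices in the annotated volume.
#' @param phase `"train"`, `"validation"`, or `"evaluation"`.
#' @return List with `box2d` (`x, y, width, height` in preprocessed
#'   pixels), `center_slice`, `slice_lo`, `slice_hi`, `lesion_class`,
#'   `lesion_type`.
#' @export
gt_box_3d <- function(annotation, n_slices,
                      phase = c("train", "validation", "evaluation")) {
  phase <- match.arg(phase)
  pp <- annotations_to_preprocessed(annotation)
  count <- positive_slice_count(annotation$Width, annotation$Height)
  rng <- switch(phase,
    train = training_slice_range(annotation$Slice, count, n_slices),
    validation = validation_slice_range(annotation$Slice, count, n_slices),
    evaluation = evaluation_slice_range(annotation$Slice, n_slices)
  )
  list(box2d = c(x = pp$X, y = pp$Y, width = pp$Width, height = pp$Height),
       center_slice = as.integer(annotation$Slice),
       slice_lo = rng[1], slice_hi = rng[2],
       lesion_class = annotation$Class, lesion_type = annotation$LesionType)
}
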