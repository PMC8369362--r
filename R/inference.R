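# Volume-level inference: pad slices to the grid, average per-slice grids
# within each volume half, decode, drop boxes outside the breast, and
# merge-based non-maximum suppression.

#' Pad a slice to the label grid
#'
#' Pads the bottom and right with zeros up to the next multiple of 96.
#' Because padding is bottom/right only, decoded box coordinates need no
#' shift to map back; `pad` records the added rows/cols.
#'
#' @param slice numeric matrix.
#' @return List `slice` (padded matrix), `pad = c(bottom, right)`.
#' @export
pad_to_grid <- function(slice) {
  h <- nrow(slice)
  w <- ncol(slice)
  ph <- (GRID_CELL - h %% GRID_CELL) %% GRID_CELL
  pw <- (GRID_CELL - w %% GRID_CELL) %% GRID_CELL
  if (ph == 0 && pw == 0) return(list(slice = slice, pad = c(0L, 0L)))
  out <- matrix(0, h + ph, w + pw)
  out[seq_len(h), seq_len(w)] <- slice
  list(slice = out, pad = c(as.integer(ph), as.integer(pw)))
}

#' Intersection over union of two boxes
#'
#' Standard 2-D IoU on half-open boxes `[x, x + w) x [y, y + h)`.
#'
#' @param a,b numeric vectors `c(x, y, width, height)` (positive dims).
#' @return Value in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

#' Drop predictions outside the breast region
#'
#' A box is kept iff at least half of its pixels lie inside the breast
#' mask of its slice (boundary case: exactly half is kept).
#'
#' @param boxes data.frame with `x, y, width, height, z` (and any other
#'   columns, preserved).
#' @param masks list of logical matrices, one per slice.
#' @return Filtered `boxes`; idempotent.
#' @export
filter_outside_breast <- function(boxes, masks) {
  if (nrow(boxes) == 0) return(boxes)
  nr <- nrow(masks[[1]])
  nc <- ncol(masks[[1]])
  keep <- vapply(seq_len(nrow(boxes)), function(i) {
    z <- boxes$z[i]
    if (z < 0 || z >= length(masks) || is.null(masks[[z + 1]]))
      stop_dbt("validation", "no breast mask for slice ", z)
    m <- masks[[z + 1]]
    c0 <- max(0, floor(boxes$x[i]))
    c1 <- min(nc - 1, ceiling(boxes$x[i] + boxes$width[i]) - 1)
    r0 <- max(0, floor(boxes$y[i]))
    r1 <- min(nr - 1, ceiling(boxes$y[i] + boxes$height[i]) - 1)
    if (c1 < c0 || r1 < r0) return(FALSE)
    inside <- sum(m[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)])
    inside >= 0.5 * boxes$width[i] * boxes$height[i]
  }, logical(1))
  boxes[keep, , drop = FALSE]
}

#' Merge-based non-maximum suppression
#'
#' While any pair of boxes has a confidence-score ratio below 10 and an
#' IoU above 0.5, the pair with the highest IoU (ties: higher max score,
#' then first in order) is merged into one box that keeps the
#' higher-scoring member's geometry and slice index and takes the maximum
#' of the two scores. Runs to a fixed point; never increases the box
#' count, and the surviving set contains no qualifying pair.
#'
#' @param boxes data.frame with `x, y, width, height, score` (> 0) and
#'   optionally `z`.
#' @param score_ratio_max merge only pairs with
#'   `max(s_i, s_j) / min(s_i, s_j) <` this value (default 10).
#' @param iou_min merge only pairs with IoU strictly greater (default 0.5).
#' @return data.frame of merged boxes.
#' @export
merge_nms <- function(boxes, score_ratio_max = 10, iou_min = 0.5) {
  if (nrow(boxes) == 0) return(boxes)
  if (any(boxes$score <= 0)) stop_dbt("parameter", "scores must be > 0")
  repeat {
    n <- nrow(boxes)
    if (n < 2) break
    best <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        si <- boxes$score[i]
        sj <- boxes$score[j]
        if (max(si, sj) / min(si, sj) >= score_ratio_max) next
        ov <- iou(as.numeric(boxes[i, c("x", "y", "width", "height")]),
                  as.numeric(boxes[j, c("x", "y", "width", "height")]))
        if (ov <= iou_min) next
        cand <- c(ov, max(si, sj), i, j)
        if (is.null(best) || cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] > best[2])) best <- cand
      }
    }
    if (is.null(best)) break
    i <- best[3]
    j <- best[4]
    win <- if (boxes$score[i] >= boxes$score[j]) i else j
    merged <- boxes[win, , drop = FALSE]
    merged$score <- max(boxes$score[i], boxes$score[j])
    boxes <- rbind(merged, boxes[-c(i, j), , drop = FALSE])
  }
  rownames(boxes) <- NULL
  boxes
}

#' Predict boxes for a whole volume
#'
#' The volume's slices are split into two halves, `[0, N/2)` and
#' `[N/2, N)` (floor split; a single-slice volume is one "half"). Within
#' each half the per-slice confidence and regression grids are averaged
#' elementwise, the averaged grid is decoded, and every resulting box gets
#' the half's middle slice as its `z`. Boxes from both halves are then
#' passed through [filter_outside_breast()] and [merge_nms()].
#'
#' @param detector a `dbt_detector`.
#' @param volume a preprocessed `dbt_volume`.
#' @param masks per-slice breast masks from [preprocess_volume()].
#' @param threshold decoding confidence threshold (default 0.05; the FROC
#'   sweep spans thresholds anyway).
#' @return data.frame in the predictions schema
#'   (`PatientID,...,X,Y,Width,Height,Z,Score`), preprocessed coordinates.
#' @export
predict_volume <- function(detector, volume, masks, threshold = 0.05) {
  ns <- n_slices(volume)
  if (ns == 0) stop_dbt("validation", "empty volume")
  half1 <- seq_len(ns %/% 2)
  halves <- if (ns == 1 || length(half1) == 0) list(seq_len(ns))
            else list(half1, (ns %/% 2 + 1):ns)
  boxes <- NULL
  for (h in halves) {
    conf_sum <- NULL
    reg_sum <- NULL
    for (k in h) {
      g <- detector_forward(detector,
                            pad_to_grid(volume$pixels[, , k])$slice)
      if (is.null(conf_sum)) {
        conf_sum <- g$confidence
        reg_sum <- g$regression
      } else {
        conf_sum <- conf_sum + g$confidence
        reg_sum <- reg_sum + g$regression
      }
    }
    grid <- structure(list(confidence = conf_sum / length(h),
                           regression = reg_sum / length(h)),
                      class = "dbt_grid")
    dec <- decode_predictions(grid, threshold)
    if (nrow(dec) > 0) {
      dec$z <- (min(h) - 1L + max(h) - 1L) %/% 2L
      boxes <- rbind(boxes, dec)
    }
  }
  if (is.null(boxes))
    boxes <- data.frame(x = numeric(0), y = numeric(0), width = numeric(0),
                        height = numeric(0), score = numeric(0),
                        z = integer(0))
  boxes <- filter_outside_breast(boxes, masks)
  boxes <- merge_nms(boxes)
  data.frame(PatientID = rep(volume$patient_id, nrow(boxes)),
             StudyUID = rep(volume$study_id, nrow(boxes)),
             View = rep(volume$view, nrow(boxes)),
             X = boxes$x, Y = boxes$y, Width = boxes$width,
             Height = boxes$height, Z = boxes$z, Score = boxes$score,
             stringsAsFactors = FALSE)
}
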