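# FROC analysis with the custom true-positive criteria: a prediction hits
# a ground-truth lesion when its 2-D center is closer than
# max(half the GT diagonal, 100 px) to the GT center and its slice falls
# in the 25%-of-slices window around the GT center slice. Curves are
# reported per volume or per breast, with bootstrap CIs over patients.

#' True-positive matching criteria
#'
#' @param distance_floor minimum allowed center distance in (preprocessed)
#'   pixels; protects very small lesions with unclear boundaries.
#' @param diagonal_fraction fraction of the GT box diagonal allowed as
#'   center distance.
#' @param z_fraction fraction of volume slices the GT box is assumed to
#'   span before and after its center slice.
#' @param require_center_in_gt stricter optional rule: additionally require
#'   the predicted center to lie inside the GT rectangle.
#' @return A `dbt_match_criteria`.
#' @export
match_criteria <- function(distance_floor = 100, diagonal_fraction = 0.5,
                           z_fraction = 0.25, require_center_in_gt = FALSE) {
  if (distance_floor <= 0 || diagonal_fraction <= 0 || z_fraction <= 0)
    stop_dbt("parameter", "criteria must be positive")
  structure(list(distance_floor = distance_floor,
                 diagonal_fraction = diagonal_fraction,
                 z_fraction = z_fraction,
                 require_center_in_gt = require_center_in_gt),
            class = "dbt_match_criteria")
}

#' Is a predicted box a true positive for a ground-truth box?
#'
#' Both boxes must be in the same (preprocessed) coordinate space.
#'
#' @param pred list/one-row data.frame with `x, y, width, height, z`.
#' @param gt list with `x, y, width, height, center_slice`.
#' @param n_slices slices in the volume.
#' @param criteria a [match_criteria()].
#' @param use_z set `FALSE` for 2-D (per-slice/crop) evaluation.
#' @return Logical.
#' @export
is_true_positive <- function(pred, gt, n_slices, criteria = match_criteria(),
                             use_z = TRUE) {
  pcx <- pred$x + pred$width / 2
  pcy <- pred$y + pred$height / 2
  gcx <- gt$x + gt$width / 2
  gcy <- gt$y + gt$height / 2
  diag_gt <- sqrt(gt$width^2 + gt$height^2)
  lim <- max(criteria$diagonal_fraction * diag_gt, criteria$distance_floor)
  d <- sqrt((pcx - gcx)^2 + (pcy - gcy)^2)
  ok <- d < lim
  if (ok && criteria$require_center_in_gt)
    ok <- pcx >= gt$x && pcx < gt$x + gt$width &&
      pcy >= gt$y && pcy < gt$y + gt$height
  if (ok && use_z) {
    rng <- evaluation_slice_range(gt$center_slice, n_slices,
                                  criteria$z_fraction)
    ok <- pred$z >= rng[1] && pred$z <= rng[2]
  }
  ok
}

# Greedy matching, one volume: predictions in descending score order claim
# the nearest unmatched GT they hit. Returns per-prediction TP flags and
# per-GT detection scores (the score threshold at which the GT first
# becomes detected; NA = never).
match_volume <- function(pred, gt, n_slices, criteria, use_z = TRUE) {
  det_score <- rep(NA_real_, nrow(gt))
  tp <- rep(FALSE, nrow(pred))
  if (nrow(pred) > 0) {
    ord <- order(-pred$Score)
    for (i in ord) {
      if (nrow(gt) == 0) break
      p <- list(x = pred$X[i], y = pred$Y[i], width = pred$Width[i],
                height = pred$Height[i], z = pred$Z[i])
      best <- NA_integer_
      best_d <- Inf
      for (j in seq_len(nrow(gt))) {
        if (!is.na(det_score[j])) next
        g <- list(x = gt$X[j], y = gt$Y[j], width = gt$Width[j],
                  height = gt$Height[j], center_slice = gt$Slice[j])
        if (!is_true_positive(p, g, n_slices, criteria, use_z)) next
        d <- sqrt((p$x + p$width / 2 - (g$x + g$width / 2))^2 +
                    (p$y + p$height / 2 - (g$y + g$height / 2))^2)
        if (d < best_d) {
          best_d <- d
          best <- j
        }
      }
      if (!is.na(best)) {
        det_score[best] <- pred$Score[i]
        tp[i] <- TRUE
      }
    }
  }
  list(tp = tp, det_score = det_score)
}

# Shared matcher over a whole prediction/GT table set. Returns flat vectors
# describing every prediction (score, tp) and every GT (det_score, keys).
match_all <- function(predictions, ground_truths, volumes,
                      criteria = match_criteria()) {
  keys <- vkey(volumes$PatientID, volumes$StudyUID, volumes$View)
  if (anyDuplicated(keys)) stop_dbt("validation", "duplicate volume keys")
  pk <- vkey(predictions$PatientID, predictions$StudyUID, predictions$View)
  gk <- vkey(ground_truths$PatientID, ground_truths$StudyUID,
             ground_truths$View)
  if (!all(gk %in% keys))
    stop_dbt("validation", "ground truth refers to unindexed volumes")
  psplit <- split(seq_len(nrow(predictions)), factor(pk, levels = keys))
  gsplit <- split(seq_len(nrow(ground_truths)), factor(gk, levels = keys))
  # vectorized greedy matcher: same rule as is_true_positive()/
  # match_volume(), applied to all GTs of a volume at once (the
  # equivalence is pinned by the exhaustive-oracle tests)
  pS <- predictions$Score
  pcx <- predictions$X + predictions$Width / 2
  pcy <- predictions$Y + predictions$Height / 2
  pZ <- predictions$Z
  gcx <- ground_truths$X + ground_truths$Width / 2
  gcy <- ground_truths$Y + ground_truths$Height / 2
  glim <- pmax(criteria$diagonal_fraction *
                 sqrt(ground_truths$Width^2 + ground_truths$Height^2),
               criteria$distance_floor)
  det_score <- rep(NA_real_, nrow(ground_truths))
  tp <- rep(FALSE, nrow(predictions))
  for (k in seq_along(keys)) {
    pi <- psplit[[k]]
    gi <- gsplit[[k]]
    if (length(pi) == 0 || length(gi) == 0) next
    ns <- volumes$NumSlices[k]
    dz <- round(criteria$z_fraction * ns)
    zlo <- pmax(0, ground_truths$Slice[gi] - dz)
    zhi <- pmin(ns - 1, ground_truths$Slice[gi] + dz)
    for (i in pi[order(-pS[pi])]) {
      d <- sqrt((pcx[i] - gcx[gi])^2 + (pcy[i] - gcy[gi])^2)
      elig <- is.na(det_score[gi]) & d < glim[gi] &
        pZ[i] >= zlo & pZ[i] <= zhi
      if (criteria$require_center_in_gt)
        elig <- elig & pcx[i] >= ground_truths$X[gi] &
          pcx[i] < ground_truths$X[gi] + ground_truths$Width[gi] &
          pcy[i] >= ground_truths$Y[gi] &
          pcy[i] < ground_truths$Y[gi] + ground_truths$Height[gi]
      if (any(elig)) {
        cand <- which(elig)
        j <- gi[cand[which.min(d[cand])]]
        det_score[j] <- pS[i]
        tp[i] <- TRUE
      }
    }
  }
  gt <- NULL
  if (nrow(ground_truths) > 0) {
    gt <- ground_truths
    gt$det_score <- det_score
  }
  list(scores = pS %||% numeric(0), tp = tp, gt = gt,
       n_volumes = nrow(volumes))
}

build_curve <- function(det_scores, fp_scores, n_gt, n_units, unit,
                        thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- c(det_scores[!is.na(det_scores)], fp_scores)
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  if (length(thresholds) == 0) thresholds <- 1
  pts <- data.frame(
    threshold = thresholds,
    fp_per_unit = vapply(thresholds,
                         function(t) sum(fp_scores >= t) / n_units, 0),
    sensitivity = vapply(thresholds, function(t) {
      if (n_gt == 0) return(0)
      sum(!is.na(det_scores) & det_scores >= t) / n_gt
    }, 0)
  )
  pts <- pts[order(pts$fp_per_unit, pts$sensitivity), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, unit = unit, n_gt = n_gt, n_units = n_units),
            class = "dbt_froc")
}

#' @export
print.dbt_froc <- function(x, ...) {
  cat(sprintf("<dbt_froc> unit=%s, %d points, %d lesions over %d units\n",
              x$unit, nrow(x$points), x$n_gt, x$n_units))
  invisible(x)
}

#' Plot an FROC curve
#' @param x a `dbt_froc`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dbt_froc <- function(x, ...) {
  graphics::plot(x$points$fp_per_unit, x$points$sensitivity, type = "s",
                 xlab = paste0("False positives per ", x$unit),
                 ylab = "Sensitivity", ylim = c(0, 1), ...)
  invisible(x)
}

#' Volume-based FROC curve
#'
#' Sweeps the score threshold over all observed scores. At each threshold,
#' predictions (descending score) are greedily matched one-to-one to
#' ground-truth lesions; sensitivity is the fraction of lesions detected
#' and the FP rate is the number of unmatched predictions divided by the
#' number of volumes -- all volumes, including lesion-free normal and
#' actionable ones.
#'
#' @param predictions data.frame in the predictions schema (preprocessed
#'   coordinates).
#' @param ground_truths data.frame in the annotations schema, in the same
#'   coordinate space as `predictions` (see
#'   [annotations_to_preprocessed()]).
#' @param volumes data.frame in the volume-index schema (every evaluated
#'   volume, with `NumSlices`).
#' @param criteria a [match_criteria()].
#' @return A `dbt_froc` whose `points` are sorted by FP rate with
#'   nondecreasing sensitivity.
#' @export
froc_volume <- function(predictions, ground_truths, volumes,
                        criteria = match_criteria()) {
  m <- match_all(predictions, ground_truths, volumes, criteria)
  det <- if (is.null(m$gt)) numeric(0) else m$gt$det_score
  build_curve(det, m$scores[!m$tp], length(det), m$n_volumes, "volume",
              thresholds = m$scores)
}

#' Breast-based FROC curve
#'
#' A breast (patient, study, laterality from the view name) with at least
#' one annotated lesion counts as detected at a threshold iff any of its
#' lesions on any view is matched. Sensitivity is over breasts with
#' lesions; the FP rate stays per volume.
#'
#' @inheritParams froc_volume
#' @return A `dbt_froc` with `unit = "breast"` sensitivity and per-volume
#'   FP rates.
#' @export
froc_breast <- function(predictions, ground_truths, volumes,
                        criteria = match_criteria()) {
  m <- match_all(predictions, ground_truths, volumes, criteria)
  if (is.null(m$gt) || nrow(m$gt) == 0) {
    return(build_curve(numeric(0), m$scores[!m$tp], 0, m$n_volumes,
                       "breast", thresholds = m$scores))
  }
  lat <- substr(m$gt$View, 1, 1)
  if (!all(lat %in% c("L", "R")))
    stop_dbt("validation", "cannot parse laterality from view name")
  breast <- paste(m$gt$PatientID, m$gt$StudyUID, lat, sep = "|")
  det <- vapply(split(m$gt$det_score, breast), function(s) {
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
  }, 0)
  build_curve(det, m$scores[!m$tp], length(det), m$n_volumes, "breast",
              thresholds = m$scores)
}

#' Sensitivity at a given FP rate
#'
#' Step-function reading of the curve: the sensitivity of the rightmost
#' point with `fp_per_unit <= fp_rate` (no interpolation); 0 when no point
#' qualifies.
#'
#' @param curve a `dbt_froc`.
#' @param fp_rate allowed false positives per unit (>= 0).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at <- function(curve, fp_rate = 2) {
  if (fp_rate < 0) stop_dbt("parameter", "fp_rate must be >= 0")
  pts <- curve$points
  if (is.null(pts) || nrow(pts) == 0) stop_dbt("validation", "empty curve")
  ok <- pts$fp_per_unit <= fp_rate
  if (!any(ok)) return(0)
  max(pts$sensitivity[ok])
}

#' Bootstrap confidence interval for an FROC metric
#'
#' Resamples patients (the independence unit; volumes of one patient stay
#' together) with replacement, recomputes the metric on each resample, and
#' returns the percentile interval. Resamples that draw no ground-truth
#' lesion are redrawn; the redraw count is attached as an attribute.
#'
#' @param predictions,ground_truths,volumes as in [froc_volume()].
#' @param metric function `(predictions, ground_truths, volumes) -> number`.
#' @param n_boot number of bootstrap replicates (2000 by convention).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed; the interval is deterministic given it.
#' @return `c(lo, hi)` with attributes `replicates` and `redraws`.
#' @export
bootstrap_ci <- function(predictions, ground_truths, volumes, metric,
                         n_boot = 2000, level = 0.95, seed = 1) {
  patients <- unique(volumes$PatientID)
  if (length(patients) < 1) stop_dbt("validation", "no resampling units")
  vals <- numeric(n_boot)
  redraws <- 0L
  # row indices per patient, computed once; a drawn patient keeps all its
  # volumes/lesions together, duplicates get distinct pseudo-identities
  vol_idx <- split(seq_len(nrow(volumes)),
                   factor(volumes$PatientID, levels = patients))
  pred_idx <- split(seq_len(nrow(predictions)),
                    factor(predictions$PatientID, levels = patients))
  gt_idx <- split(seq_len(nrow(ground_truths)),
                  factor(ground_truths$PatientID, levels = patients))
  resample <- function(df, idx, draw, tag) {
    take <- idx[draw]
    out <- df[unlist(take, use.names = FALSE), , drop = FALSE]
    out$PatientID <- rep(tag, lengths(take))
    out
  }
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        draw <- sample(patients, length(patients), replace = TRUE)
        tag <- paste0(draw, "#", seq_along(draw))
        if (sum(lengths(gt_idx[draw])) > 0) break
        redraws <- redraws + 1L
      }
      vals[b] <- metric(resample(predictions, pred_idx, draw, tag),
                        resample(ground_truths, gt_idx, draw, tag),
                        resample(volumes, vol_idx, draw, tag))
    }
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(vals, c(alpha, 1 - alpha)))
  attr(ci, "replicates") <- vals
  attr(ci, "redraws") <- redraws
  ci
}
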