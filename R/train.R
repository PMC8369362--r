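# Training protocol: epochs iterate the positive lesions only (background
# cells inside each crop supply the negatives), Adam with early stopping,
# per-epoch validation by 2-D sensitivity at 2 FP/slice on fixed crops,
# and cross-loss model selection by 3-D sensitivity at 2 FP/volume.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 0.001, batch size 16, up to 100 epochs over positive examples, early
#' stopping with patience 25, and 1056 x 672-px training crops. The crop
#' may be shrunk (multiples of 96) for desk-scale runs on phantom data.
#'
#' @param learning_rate Adam initial learning rate.
#' @param batch_size examples per optimization step.
#' @param max_epochs maximum epochs.
#' @param patience epochs without validation improvement before stopping
#'   (must be `< max_epochs`).
#' @param crop `c(width, height)` of training crops, multiples of 96.
#' @param seed RNG seed for sampling and shuffling.
#' @param loss a [loss_config()].
#' @param lambda weight of the localization term in the total loss.
#' @return A `dbt_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L,
                         max_epochs = 100L, patience = 25L,
                         crop = c(1056L, 672L), seed = 1L,
                         loss = loss_config("focal"), lambda = 1) {
  if (patience >= max_epochs)
    stop_dbt("config", "patience must be < max_epochs")
  if (any(crop %% GRID_CELL != 0))
    stop_dbt("config", "crop dims must be multiples of 96")
  if (!inherits(loss, "dbt_loss_config"))
    stop_dbt("config", "loss must be a loss_config()")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 crop = as.integer(crop), seed = as.integer(seed),
                 loss = loss, lambda = lambda),
            class = "dbt_train_config")
}

# zero-padded crop extraction; (x0, y0) 0-based top-left in image coords
extract_crop <- function(slice, x0, y0, cw, ch) {
  out <- matrix(0, ch, cw)
  r0 <- max(0, y0)
  r1 <- min(nrow(slice) - 1, y0 + ch - 1)
  c0 <- max(0, x0)
  c1 <- min(ncol(slice) - 1, x0 + cw - 1)
  if (r1 >= r0 && c1 >= c0)
    out[(r0 - y0 + 1):(r1 - y0 + 1), (c0 - x0 + 1):(c1 - x0 + 1)] <-
      slice[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)]
  out
}

sample_int_range <- function(lo, hi) {
  if (lo >= hi) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

crop_offset_range <- function(b0, blen, clen, img) {
  # offsets that keep [b0, b0 + blen) fully inside a clen-wide crop that
  # itself stays inside (or zero-pads beyond) the img-wide image
  if (img < clen) {
    if (blen <= clen) return(c(0L, 0L))
    return(NULL)
  }
  lo <- max(0, b0 + blen - clen)
  hi <- min(b0, img - clen)
  if (lo > hi) return(NULL)
  c(as.integer(floor(lo)), as.integer(floor(hi)))
}

#' Sample a training example for one lesion
#'
#' Draws a slice uniformly from the lesion's training slice span and a
#' crop offset uniformly among the offsets that fully contain the 2-D
#' ground-truth box (clipped to the image; zero-padded when the image is
#' smaller than the crop). A box larger than the crop is center-cropped
#' with a warning. Randomness comes from R's RNG, so a fixed seed gives an
#' identical sample sequence.
#'
#' @param gt a [gt_box_3d()] with `phase = "train"`.
#' @param volume the preprocessed `dbt_volume` the lesion lives in.
#' @param crop `c(width, height)` in pixels, multiples of 96.
#' @return List `image` (crop matrix), `target` (a `dbt_target_grid`),
#'   `box` (box in crop coordinates), `z` (sampled slice).
#' @export
sample_training_example <- function(gt, volume, crop = c(1056L, 672L)) {
  cw <- crop[1]
  ch <- crop[2]
  z <- sample_int_range(gt$slice_lo, gt$slice_hi)
  b <- gt$box2d
  sl <- volume$pixels[, , z + 1L]
  xr <- crop_offset_range(b["x"], b["width"], cw, ncol(sl))
  yr <- crop_offset_range(b["y"], b["height"], ch, nrow(sl))
  if (is.null(xr) || is.null(yr)) {
    warning("ground-truth box larger than crop; center-cropping")
    x0 <- as.integer(round(b["x"] + b["width"] / 2 - cw / 2))
    y0 <- as.integer(round(b["y"] + b["height"] / 2 - ch / 2))
  } else {
    x0 <- sample_int_range(xr[1], xr[2])
    y0 <- sample_int_range(yr[1], yr[2])
  }
  box <- data.frame(x = as.numeric(b["x"]) - x0, y = as.numeric(b["y"]) - y0,
                    width = as.numeric(b["width"]),
                    height = as.numeric(b["height"]))
  box$x <- clamp(box$x, -box$width / 2 + 1e-9, cw - box$width / 2 - 1e-9)
  box$y <- clamp(box$y, -box$height / 2 + 1e-9, ch - box$height / 2 - 1e-9)
  list(image = extract_crop(sl, x0, y0, cw, ch),
       target = encode_target_grid(box, c(ch, cw)), box = box, z = z)
}

#' Deterministic validation example for one lesion
#'
#' Uses the middle slice of the (halved) validation slice span and a crop
#' centered on the box, clipped to the image; identical across epochs and
#' runs.
#'
#' @param gt a [gt_box_3d()] with `phase = "validation"`.
#' @inheritParams sample_training_example
#' @return Same structure as [sample_training_example()].
#' @export
fixed_validation_example <- function(gt, volume, crop = c(1056L, 672L)) {
  cw <- crop[1]
  ch <- crop[2]
  z <- (gt$slice_lo + gt$slice_hi) %/% 2L
  b <- gt$box2d
  sl <- volume$pixels[, , z + 1L]
  x0 <- as.integer(clamp(round(b["x"] + b["width"] / 2 - cw / 2), 0,
                         max(0, ncol(sl) - cw)))
  y0 <- as.integer(clamp(round(b["y"] + b["height"] / 2 - ch / 2), 0,
                         max(0, nrow(sl) - ch)))
  box <- data.frame(x = as.numeric(b["x"]) - x0, y = as.numeric(b["y"]) - y0,
                    width = as.numeric(b["width"]),
                    height = as.numeric(b["height"]))
  box$x <- clamp(box$x, -box$width / 2 + 1e-9, cw - box$width / 2 - 1e-9)
  box$y <- clamp(box$y, -box$height / 2 + 1e-9, ch - box$height / 2 - 1e-9)
  list(image = extract_crop(sl, x0, y0, cw, ch),
       target = encode_target_grid(box, c(ch, cw)), box = box, z = z)
}

#' Slice-level (2-D) FROC over fixed crops
#'
#' Used for validation-time model selection: each crop is the unit, a
#' prediction hits a box by the same center-distance rule as the 3-D
#' evaluation but without the slice condition.
#'
#' @param pred_list list (one per crop) of data.frames
#'   `x, y, width, height, score`.
#' @param gt_list list (one per crop) of data.frames `x, y, width, height`.
#' @param criteria a [match_criteria()].
#' @return A `dbt_froc` with `unit = "slice"`.
#' @export
froc_slice <- function(pred_list, gt_list, criteria = match_criteria()) {
  det <- numeric(0)
  fp_scores <- numeric(0)
  all_scores <- numeric(0)
  for (i in seq_along(pred_list)) {
    p <- pred_list[[i]]
    g <- gt_list[[i]]
    pdf <- data.frame(X = p$x, Y = p$y, Width = p$width, Height = p$height,
                      Z = 0L, Score = p$score)
    gdf <- data.frame(X = g$x, Y = g$y, Width = g$width, Height = g$height,
                      Slice = 0L)
    m <- match_volume(pdf, gdf, 1L, criteria, use_z = FALSE)
    det <- c(det, m$det_score)
    fp_scores <- c(fp_scores, pdf$Score[!m$tp])
    all_scores <- c(all_scores, pdf$Score)
  }
  build_curve(det, fp_scores, length(det), length(pred_list), "slice",
              thresholds = all_scores)
}

validation_sensitivity <- function(detector, val_examples, fp_rate = 2) {
  preds <- lapply(val_examples, function(ex) {
    decode_predictions(detector_forward(detector, ex$image), threshold = 0)
  })
  gts <- lapply(val_examples, `[[`, "box")
  sensitivity_at(froc_slice(preds, gts), fp_rate)
}

# validation sensitivity plus mean validation loss (the loss is used only
# to break ties in the sensitivity, which saturates quickly at desk scale
# because the 100-px matching floor is large relative to small crops)
validation_metrics <- function(detector, val_examples, cfg, lambda, w,
                               fp_rate = 2) {
  loss <- 0
  for (ex in val_examples) {
    fw <- nn_forward(detector, ex$image)
    loss <- loss + head_loss_grads(fw$head, ex$target, cfg, lambda, w)$loss
  }
  list(sensitivity = validation_sensitivity(detector, val_examples, fp_rate),
       loss = loss / max(1, length(val_examples)))
}

# gradient of (objectness + lambda * localization) w.r.t. the raw head
head_loss_grads <- function(head, target, cfg, lambda, w) {
  dn <- dim(head)
  ncells <- dn[1] * dn[2]
  conf <- sigmoid(matrix(head[, , 1], dn[1], dn[2]))
  tobj <- target$objectness
  l_obj <- objectness_loss(conf, tobj, cfg, w)
  g1 <- objectness_grad_logit(conf, tobj, cfg, w) / ncells
  off_x <- tanh(head[, , 2]) / 2
  off_y <- tanh(head[, , 3]) / 2
  pred_reg <- array(0, dim = c(dn[1], dn[2], 4))
  pred_reg[, , 1] <- off_x
  pred_reg[, , 2] <- off_y
  pred_reg[, , 3] <- head[, , 4]
  pred_reg[, , 4] <- head[, , 5]
  l_loc <- localization_mse(pred_reg, target$regression, tobj)
  ghead <- array(0, dim = dn)
  ghead[, , 1] <- g1
  npos <- sum(tobj > 0)
  if (npos > 0) {
    resid <- (pred_reg - target$regression) * 2 / (4 * npos) * lambda
    mask <- tobj > 0
    act <- array(1, dim = c(dn[1], dn[2], 4))
    act[, , 1] <- (1 - (2 * off_x)^2) / 2
    act[, , 2] <- (1 - (2 * off_y)^2) / 2
    for (ch in 1:4) {
      gch <- resid[, , ch] * act[, , ch]
      gch[!mask] <- 0
      ghead[, , ch + 1] <- gch
    }
  }
  list(ghead = ghead, loss = l_obj + lambda * l_loc, obj = l_obj,
       loc = l_loc)
}

#' Assemble training cases from annotations and preprocessed volumes
#'
#' @param annotations data.frame in the [read_annotations()] schema
#'   (full-resolution coordinates).
#' @param volumes named list of preprocessed `dbt_volume`s keyed by
#'   `PatientID|StudyUID|View`.
#' @param phase passed to [gt_box_3d()].
#' @return List of cases, each `list(gt, volume)`.
#' @export
build_cases <- function(annotations, volumes, phase = "train") {
  lapply(seq_len(nrow(annotations)), function(i) {
    ann <- annotations[i, , drop = FALSE]
    key <- vkey(ann$PatientID, ann$StudyUID, ann$View)
    vol <- volumes[[key]]
    if (is.null(vol)) stop_dbt("validation", "no volume for ", key)
    list(gt = gt_box_3d(ann, n_slices(vol), phase), volume = vol)
  })
}

#' Train a detector
#'
#' One epoch is one pass over all positive lesions (each contributing one
#' randomly sampled crop); background cells inside the crops supply the
#' negatives. After every epoch the 2-D sensitivity at 2 FP/slice is
#' computed on the fixed validation crops; the parameters with the best
#' validation metric are kept, and training stops after `patience` epochs
#' without improvement or at `max_epochs`.
#'
#' @param detector a freshly built (or warm) `dbt_detector`.
#' @param train_cases,val_cases case lists from [build_cases()]
#'   (`phase = "train"` and `"validation"` respectively).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return List `detector` (best checkpoint), `history` (data.frame
#'   `epoch, loss, val_sensitivity`), `best_epoch`, `best_metric`.
#' @export
train <- function(detector, train_cases, val_cases, config = train_config(),
                  verbose = FALSE) {
  if (length(train_cases) == 0)
    stop_dbt("config", "empty training set")
  val_examples <- lapply(val_cases, function(cs)
    fixed_validation_example(cs$gt, cs$volume, config$crop))
  # prevalence of positive cells: one box per crop over the grid area
  ncells <- prod(config$crop %/% GRID_CELL)
  w <- prevalence_weights(1 / ncells)
  state <- adam_init(detector$params)
  best <- list(params = detector$params, metric = -Inf, loss = Inf,
               epoch = 0L)
  history <- NULL
  with_seed(config$seed, {
    since_best <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(train_cases))
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        gacc <- NULL
        bl <- 0
        for (i in idx) {
          cs <- train_cases[[i]]
          ex <- sample_training_example(cs$gt, cs$volume, config$crop)
          fw <- nn_forward(detector, ex$image, keep_cache = TRUE)
          hl <- head_loss_grads(fw$head, ex$target, config$loss,
                                config$lambda, w)
          g <- nn_backward(detector, fw$cache, hl$ghead)
          gacc <- if (is.null(gacc)) g else grads_add(gacc, g)
          bl <- bl + hl$loss
        }
        gacc <- grads_scale(gacc, 1 / length(idx))
        stepped <- adam_step(detector$params, gacc, state,
                             config$learning_rate)
        detector$params <- stepped$params
        state <- stepped$state
        epoch_loss <- epoch_loss + bl / length(idx)
        nb <- nb + 1L
      }
      epoch_loss <- epoch_loss / nb
      vm <- if (length(val_examples) > 0)
        validation_metrics(detector, val_examples, config$loss,
                           config$lambda, w)
      else list(sensitivity = -epoch_loss, loss = epoch_loss)
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = epoch_loss,
                                  val_sensitivity = vm$sensitivity,
                                  val_loss = vm$loss))
      if (verbose)
        message(sprintf(
          "epoch %3d  loss %.5f  val sens@2FP/slice %.3f  val loss %.5f",
          epoch, epoch_loss, vm$sensitivity, vm$loss))
      improved <- vm$sensitivity > best$metric ||
        (vm$sensitivity == best$metric && vm$loss < best$loss)
      if (improved) {
        best <- list(params = detector$params, metric = vm$sensitivity,
                     loss = vm$loss, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })
  detector$params <- best$params
  list(detector = detector, history = history, best_epoch = best$epoch,
       best_metric = best$metric)
}

#' Select the best candidate model by 3-D volume evaluation
#'
#' Runs full volume inference and the volume-based FROC for every
#' candidate and returns the one with the highest sensitivity at
#' `fp_rate` FP/volume. Ties are broken by the lower FP rate at which that
#' sensitivity is reached, then by listed order.
#'
#' @param candidates list of `list(loss_kind, detector)`.
#' @param val_volumes list of `list(volume, masks)` (preprocessed).
#' @param annotations annotations for the validation volumes
#'   (full-resolution; converted internally).
#' @param index volume-index data.frame covering `val_volumes`.
#' @param fp_rate operating point (default 2 FP/volume).
#' @param criteria a [match_criteria()].
#' @return The winning candidate, with `sensitivity` and `curve` attached.
#' @export
select_model <- function(candidates, val_volumes, annotations, index,
                         fp_rate = 2, criteria = match_criteria()) {
  if (length(candidates) == 0) stop_dbt("config", "no candidates")
  gt_pp <- annotations_to_preprocessed(annotations)
  best <- NULL
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    preds <- do.call(rbind, lapply(val_volumes, function(v)
      predict_volume(cand$detector, v$volume, v$masks)))
    curve <- froc_volume(preds, gt_pp, index, criteria)
    s <- sensitivity_at(curve, fp_rate)
    ok <- curve$points$sensitivity >= s - 1e-12
    fp_at <- if (any(ok)) min(curve$points$fp_per_unit[ok]) else Inf
    score <- c(s, -fp_at)
    if (is.null(best) || score[1] > best$score[1] ||
        (score[1] == best$score[1] && score[2] > best$score[2])) {
      cand$sensitivity <- s
      cand$curve <- curve
      cand$score <- score
      best <- cand
    }
  }
  best
}
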