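# Public detector interface: configuration, deterministic construction,
# fully convolutional forward pass, and prediction decoding.

#' Detector configuration
#'
#' A single-phase, fully convolutional 2-D detector with a dense-block
#' backbone. The pooling schedule (one 2x pool after the stem and after
#' each of the four dense blocks, then a final 3x pool) fixes the total
#' stride at 96, so the output grid has one cell per 96 x 96-px input
#' tile and 5 channels per cell (1 confidence logit + 4 box regression
#' values). Exactly four dense blocks are required; any other block count
#' cannot realize stride 96 with this schedule.
#'
#' The default width (`growth_rate = 8`, `blocks = c(2, 2, 2, 2)`) is sized
#' for CPU training on phantom data.
#'
#' @param growth_rate channels added by each dense-block layer.
#' @param blocks integer vector of layers per dense block (length 4).
#' @param stem_channels channels after the stem convolution.
#' @param prior expected foreground prevalence used to initialize the
#'   confidence bias to `-log((1 - prior) / prior)`.
#' @param seed integer seed making construction deterministic.
#' @return A `dbt_detector_config`.
#' @export
detector_config <- function(growth_rate = 8L, blocks = c(2L, 2L, 2L, 2L),
                            stem_channels = 16L, prior = 0.01, seed = 1L) {
  if (length(blocks) != 4L || any(blocks < 1L))
    stop_dbt("config", "stride decomposition impossible: need exactly 4 ",
             "dense blocks with >= 1 layer each")
  if (growth_rate < 1L || stem_channels < 1L)
    stop_dbt("config", "growth_rate and stem_channels must be >= 1")
  if (prior <= 0 || prior >= 1) stop_dbt("config", "prior must be in (0,1)")
  structure(
    list(growth_rate = as.integer(growth_rate), blocks = as.integer(blocks),
         stem_channels = as.integer(stem_channels), prior = prior,
         total_stride = 96L, head_channels = 5L, seed = as.integer(seed)),
    class = "dbt_detector_config"
  )
}

#' Build a detector
#'
#' Convolution weights are Kaiming-initialized (normal, sd
#' `sqrt(2 / fan_in)`); the head weights use a small normal init
#' (sd 0.01) and the confidence bias is set to `-log((1 - prior) / prior)`
#' so that a fresh detector predicts confidence about `prior` everywhere,
#' which stabilizes training under extreme class imbalance. Construction
#' is deterministic given `config$seed`.
#'
#' @param config a [detector_config()].
#' @return A `dbt_detector` (config + parameter tensors).
#' @export
build_detector <- function(config) {
  if (!inherits(config, "dbt_detector_config"))
    config <- do.call(detector_config, config)
  with_seed(config$seed, {
    params <- list()
    fan <- 9L * 1L
    params$stem <- list(
      W = matrix(stats::rnorm(fan * config$stem_channels, sd = sqrt(2 / fan)),
                 fan, config$stem_channels),
      b = rep(0, config$stem_channels)
    )
    params$blocks <- vector("list", length(config$blocks))
    cin <- config$stem_channels
    for (b in seq_along(config$blocks)) {
      params$blocks[[b]] <- vector("list", config$blocks[b])
      for (j in seq_len(config$blocks[b])) {
        fan <- 9L * cin
        params$blocks[[b]][[j]] <- list(
          W = matrix(stats::rnorm(fan * config$growth_rate,
                                  sd = sqrt(2 / fan)),
                     fan, config$growth_rate),
          b = rep(0, config$growth_rate)
        )
        cin <- cin + config$growth_rate
      }
    }
    params$head <- list(
      W = matrix(stats::rnorm(cin * config$head_channels, sd = 0.01),
                 cin, config$head_channels),
      b = c(-log((1 - config$prior) / config$prior), rep(0, 4))
    )
    structure(list(config = config, params = params), class = "dbt_detector")
  })
}

#' @export
print.dbt_detector <- function(x, ...) {
  np <- sum(unlist(param_walk(x$params, NULL,
                              function(a, b) length(a))))
  cat(sprintf("<dbt_detector> growth=%d blocks=%s stem=%d, %d parameters\n",
              x$config$growth_rate,
              paste(x$config$blocks, collapse = ","),
              x$config$stem_channels, np))
  invisible(x)
}

grid_from_head <- function(head) {
  conf <- sigmoid(head[, , 1])
  dn <- dim(head)
  reg <- array(0, dim = c(dn[1], dn[2], 4))
  reg[, , 1] <- tanh(head[, , 2]) / 2
  reg[, , 2] <- tanh(head[, , 3]) / 2
  reg[, , 3] <- head[, , 4]
  reg[, , 4] <- head[, , 5]
  structure(list(confidence = matrix(conf, dn[1], dn[2]), regression = reg),
            class = "dbt_grid")
}

#' Run the detector on 2-D slices
#'
#' Fully convolutional: any input whose dimensions are multiples of 96
#' yields a grid of shape `(rows/96, cols/96)`; callers must pad first
#' (see [pad_to_grid()]). Confidence is sigmoid-activated (strictly inside
#' (0, 1)), offsets are bounded to `[-0.5, 0.5]` by `tanh/2`, scales are
#' unbounded.
#'
#' @param detector a `dbt_detector`.
#' @param slices a numeric matrix or a list of matrices.
#' @return A `dbt_grid` (list `confidence`, `regression`) or a list of
#'   them when `slices` is a list.
#' @export
detector_forward <- function(detector, slices) {
  if (is.matrix(slices))
    return(grid_from_head(nn_forward(detector, slices)$head))
  lapply(slices, function(s) grid_from_head(nn_forward(detector, s)$head))
}

#' Decode a detection grid into scored boxes
#'
#' One candidate per cell with confidence above `threshold`:
#' `center = cell_center + 96 * offset`, `dims = 256 * exp(scale)`,
#' `score = confidence`.
#'
#' @param grid a `dbt_grid` (or a `dbt_target_grid`-shaped list with
#'   `confidence`/`regression`).
#' @param threshold confidence threshold in `[0, 1)`.
#' @return data.frame `x, y, width, height, score` in input-image (crop)
#'   coordinates.
#' @export
decode_predictions <- function(grid, threshold = 0.05) {
  if (threshold < 0 || threshold >= 1)
    stop_dbt("parameter", "threshold must be in [0, 1)")
  conf <- grid$confidence
  keep <- which(conf > threshold, arr.ind = TRUE)
  if (nrow(keep) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), width = numeric(0),
                      height = numeric(0), score = numeric(0)))
  ci <- keep[, 1] - 1
  cj <- keep[, 2] - 1
  off_x <- grid$regression[cbind(keep[, 1], keep[, 2], 1)]
  off_y <- grid$regression[cbind(keep[, 1], keep[, 2], 2)]
  sw <- grid$regression[cbind(keep[, 1], keep[, 2], 3)]
  sh <- grid$regression[cbind(keep[, 1], keep[, 2], 4)]
  cx <- cj * GRID_CELL + GRID_CELL / 2 + GRID_CELL * off_x
  cy <- ci * GRID_CELL + GRID_CELL / 2 + GRID_CELL * off_y
  wd <- ANCHOR * exp(sw)
  ht <- ANCHOR * exp(sh)
  data.frame(x = cx - wd / 2, y = cy - ht / 2, width = wd, height = ht,
             score = conf[keep])
}

#' Save / load a detector checkpoint
#'
#' Checkpoints embed the full configuration (including the seed) and the
#' parameter tensors.
#'
#' @param detector a `dbt_detector`.
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the `dbt_detector`.
#' @export
save_checkpoint <- function(detector, path) {
  saveRDS(detector, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  det <- readRDS(path)
  if (!inherits(det, "dbt_detector"))
    stop_dbt("format", "not a detector checkpoint: ", path)
  det
}
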