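# Objectness losses for the foreground/background imbalance of dense
# detection (very few cells contain a lesion center), plus the MSE
# localization loss. All take probabilities p in (0,1) and binary targets;
# probabilities are clamped at 1e-7 from both ends before the logs.

P_CLAMP <- 1e-7

clamp_p <- function(p) clamp(p, P_CLAMP, 1 - P_CLAMP)

#' Binary cross-entropy
#'
#' `-[y log p + (1 - y) log(1 - p)]`, elementwise and vectorized.
#'
#' @param p predicted probabilities in (0, 1) (clamped at 1e-7).
#' @param y binary targets (0/1).
#' @return Nonnegative loss values, same shape as `p`.
#' @export
bce <- function(p, y) {
  p <- clamp_p(p)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Weighted binary cross-entropy
#'
#' Positive and negative terms are weighted separately. By convention the
#' weights are the inverse class frequencies over the training target
#' grids, normalized so `w_pos + w_neg = 2` (a 1:99 prevalence gives
#' `w_pos / w_neg = 99`).
#'
#' @inheritParams bce
#' @param w_pos,w_neg positive weights (> 0).
#' @export
weighted_bce <- function(p, y, w_pos = 1, w_neg = 1) {
  if (w_pos <= 0 || w_neg <= 0)
    stop_dbt("parameter", "class weights must be positive")
  p <- clamp_p(p)
  -(w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p))
}

#' Prevalence-based class weights
#'
#' @param pos_fraction fraction of positive cells in the training targets.
#' @return `c(w_pos, w_neg)` with `w_pos + w_neg = 2` and
#'   `w_pos / w_neg = (1 - f) / f`.
#' @export
prevalence_weights <- function(pos_fraction) {
  f <- clamp(pos_fraction, 1e-6, 1 - 1e-6)
  c(w_pos = 2 * (1 - f), w_neg = 2 * f)
}

#' Focal loss
#'
#' Down-weights well-classified examples: for `y = 1`,
#' `-alpha (1 - p)^gamma log p`, and symmetrically (`p -> 1 - p`) for
#' `y = 0`. With `gamma = 0, alpha = 1` this is exactly [bce()].
#'
#' @inheritParams bce
#' @param alpha positive scaling factor.
#' @param gamma focusing exponent (>= 0).
#' @export
focal <- function(p, y, alpha = 0.25, gamma = 2) {
  if (alpha <= 0 || gamma < 0)
    stop_dbt("parameter", "need alpha > 0 and gamma >= 0")
  p <- clamp_p(p)
  pt <- y * p + (1 - y) * (1 - p)
  alpha * (1 - pt)^gamma * (-log(pt))
}

#' Reduced focal loss
#'
#' Equal to binary cross-entropy while the true-class probability `p_t` is
#' below `threshold`; above it, the cross-entropy is scaled by
#' `((1 - p_t) / threshold)^gamma`, which decays gradually toward the
#' focal regime. Continuous in `p` everywhere (both branches agree at
#' `p_t = threshold`), and `<= bce` for `p_t >= threshold`.
#'
#' @inheritParams bce
#' @param gamma focusing exponent (>= 0).
#' @param threshold switch point on the true-class probability, in (0, 1).
#' @export
reduced_focal <- function(p, y, gamma = 2, threshold = 0.5) {
  if (gamma < 0) stop_dbt("parameter", "gamma must be >= 0")
  if (threshold <= 0 || threshold >= 1)
    stop_dbt("parameter", "threshold must be in (0, 1)")
  p <- clamp_p(p)
  pt <- y * p + (1 - y) * (1 - p)
  base <- -log(pt)
  fr <- ifelse(pt < threshold, 1, ((1 - pt) / threshold)^gamma)
  fr * base
}

#' Localization loss (mean squared error)
#'
#' MSE over the 4 regression channels at positive cells only; 0 when there
#' are no positive cells.
#'
#' @param pred_reg,target_reg arrays `rows x cols x 4`.
#' @param positive 0/1 matrix of positive cells (`rows x cols`).
#' @export
localization_mse <- function(pred_reg, target_reg, positive) {
  if (!identical(dim(pred_reg), dim(target_reg)))
    stop_dbt("shape", "regression shapes disagree")
  idx <- which(positive > 0)
  if (length(idx) == 0) return(0)
  nc <- dim(pred_reg)[1] * dim(pred_reg)[2]
  sel <- as.vector(outer(idx, (0:3) * nc, `+`))
  mean((pred_reg[sel] - target_reg[sel])^2)
}

#' Objectness loss configuration
#'
#' @param kind one of `"bce"`, `"weighted_bce"`, `"focal"`,
#'   `"reduced_focal"`.
#' @param alpha,gamma focal parameters (defaults follow the usual focal
#'   convention, alpha 0.25, gamma 2).
#' @param reduced_threshold switch point of the reduced focal loss.
#' @param pos_weight_mode how `weighted_bce` weights are derived;
#'   `"prevalence"` uses inverse class frequency over the training grids.
#' @return A `dbt_loss_config`.
#' @export
loss_config <- function(kind = c("focal", "bce", "weighted_bce",
                                 "reduced_focal"),
                        alpha = 0.25, gamma = 2, reduced_threshold = 0.5,
                        pos_weight_mode = "prevalence") {
  kind <- match.arg(kind)
  if (reduced_threshold <= 0 || reduced_threshold >= 1)
    stop_dbt("parameter", "reduced_threshold must be in (0, 1)")
  structure(list(kind = kind, alpha = alpha, gamma = gamma,
                 reduced_threshold = reduced_threshold,
                 pos_weight_mode = pos_weight_mode),
            class = "dbt_loss_config")
}

# loss value for a confidence grid under a loss config (mean over cells)
objectness_loss <- function(conf, target, cfg, w = c(1, 1)) {
  v <- switch(cfg$kind,
    bce = bce(conf, target),
    weighted_bce = weighted_bce(conf, target, w[1], w[2]),
    focal = focal(conf, target, cfg$alpha, cfg$gamma),
    reduced_focal = reduced_focal(conf, target, cfg$gamma,
                                  cfg$reduced_threshold)
  )
  mean(v)
}

# d(per-cell loss)/d(logit), elementwise; mean reduction applied by caller
objectness_grad_logit <- function(p, y, cfg, w = c(1, 1)) {
  p <- clamp_p(p)
  switch(cfg$kind,
    bce = p - y,
    weighted_bce = w[1] * y * (p - 1) + w[2] * (1 - y) * p,
    focal = {
      a <- cfg$alpha
      g <- cfg$gamma
      y * (a * (1 - p)^g * (g * p * log(p) - (1 - p))) +
        (1 - y) * (a * p^g * (p - g * (1 - p) * log(1 - p)))
    },
    reduced_focal = {
      g <- cfg$gamma
      thr <- cfg$reduced_threshold
      pt <- y * p + (1 - y) * (1 - p)
      s <- ifelse(y == 1, 1, -1)
      low <- p - y  # plain bce branch
      A <- ((1 - pt) / thr)^g
      dA <- if (g == 0) 0 * pt else -g / thr * ((1 - pt) / thr)^(g - 1)
      B <- -log(pt)
      dB <- -1 / pt
      high <- (dA * B + A * dB) * pt * (1 - pt) * s
      ifelse(pt < thr, low, high)
    }
  )
}
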