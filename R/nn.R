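# Network internals: forward pass with caching, backpropagation, and Adam.
# Architecture (fixed topology, configurable width/depth):
#   stem 3x3 conv -> ReLU -> 2x avg pool
#   4 dense blocks (each layer: 3x3 conv -> ReLU -> concat), 2x pool after
#   each block, then a final 3x avg pool and a 1x1 5-channel head.
# Total stride 2 * 2^4 * 3 = 96, matching the label-grid cell size.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_forward <- function(detector, x, keep_cache = FALSE) {
  H <- nrow(x)
  W <- ncol(x)
  if (H %% GRID_CELL != 0 || W %% GRID_CELL != 0)
    stop_dbt("shape", "input dims must be multiples of 96, got ", H, "x", W)
  p <- detector$params
  cache <- if (keep_cache) list() else NULL
  a <- array(x, dim = c(H, W, 1L))
  # at inference (no cache) the ReLU is fused into the convolution and the
  # pre-activation tensors are not materialized
  if (keep_cache) {
    z_stem <- cpp_conv_fwd(a, p$stem$W, p$stem$b, 3L)
    r_stem <- relu(z_stem)
    cache$a <- a
    cache$z_stem <- z_stem
    cache$stem_pool_in_dim <- dim(r_stem)
  } else {
    r_stem <- cpp_conv_fwd(a, p$stem$W, p$stem$b, 3L, relu = TRUE)
  }
  cur <- cpp_avgpool_fwd(r_stem, 2L)
  blocks <- detector$config$blocks
  growth <- detector$config$growth_rate
  if (keep_cache) cache$blocks <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bc <- if (keep_cache) list(inputs = list(), zs = list()) else NULL
    feats <- cur
    for (j in seq_len(blocks[b])) {
      wj <- p$blocks[[b]][[j]]
      if (keep_cache) {
        z <- cpp_conv_fwd(feats, wj$W, wj$b, 3L)
        bc$inputs[[j]] <- feats
        bc$zs[[j]] <- z
        r <- relu(z)
      } else {
        r <- cpp_conv_fwd(feats, wj$W, wj$b, 3L, relu = TRUE)
      }
      feats <- cpp_concat(feats, r)
    }
    if (keep_cache) {
      bc$pool_in_dim <- dim(feats)
      cache$blocks[[b]] <- bc
    }
    cur <- cpp_avgpool_fwd(feats, 2L)
  }
  if (keep_cache) cache$final_pool_in_dim <- dim(cur)
  cur <- cpp_avgpool_fwd(cur, 3L)
  if (keep_cache) cache$head_in <- cur
  head <- cpp_conv_fwd(cur, p$head$W, p$head$b, 1L)
  list(head = head, cache = cache)
}

# ghead: gradient of the loss w.r.t. the raw (pre-activation) head cube.
nn_backward <- function(detector, cache, ghead) {
  p <- detector$params
  grads <- list(blocks = vector("list", length(detector$config$blocks)))
  hb <- cpp_conv_bwd(cache$head_in, p$head$W, ghead, 1L)
  grads$head <- list(W = hb$gW, b = hb$gb)
  g <- cpp_avgpool_bwd(hb$gx, 3L, cache$final_pool_in_dim[1],
                       cache$final_pool_in_dim[2])
  blocks <- detector$config$blocks
  growth <- detector$config$growth_rate
  for (b in rev(seq_along(blocks))) {
    bc <- cache$blocks[[b]]
    grads$blocks[[b]] <- vector("list", blocks[b])
    g <- cpp_avgpool_bwd(g, 2L, bc$pool_in_dim[1], bc$pool_in_dim[2])
    for (j in rev(seq_len(blocks[b]))) {
      cin <- dim(bc$inputs[[j]])[3]
      dn <- dim(g)
      g_prev <- array(g[, , seq_len(cin)], dim = c(dn[1], dn[2], cin))
      g_new <- array(g[, , cin + seq_len(growth)],
                     dim = c(dn[1], dn[2], growth))
      g_new <- g_new * (bc$zs[[j]] > 0)
      cb <- cpp_conv_bwd(bc$inputs[[j]], p$blocks[[b]][[j]]$W, g_new, 3L)
      grads$blocks[[b]][[j]] <- list(W = cb$gW, b = cb$gb)
      g <- g_prev + cb$gx
    }
  }
  g <- cpp_avgpool_bwd(g, 2L, cache$stem_pool_in_dim[1],
                       cache$stem_pool_in_dim[2])
  g <- g * (cache$z_stem > 0)
  sb <- cpp_conv_bwd(cache$a, p$stem$W, g, 3L)
  grads$stem <- list(W = sb$gW, b = sb$gb)
  grads
}

# elementwise walkers over the nested parameter structure
param_walk <- function(a, b, f) {
  if (is.list(a) && !is.null(a$W)) {
    list(W = f(a$W, if (is.null(b)) NULL else b$W),
         b = f(a$b, if (is.null(b)) NULL else b$b))
  } else if (is.list(a)) {
    out <- vector("list", length(a))
    nm <- names(a)
    names(out) <- nm
    for (k in seq_along(a)) {
      bk <- if (is.null(b)) NULL
            else if (!is.null(nm) && nzchar(nm[k])) b[[nm[k]]]
            else b[[k]]
      out[[k]] <- param_walk(a[[k]], bk, f)
    }
    out
  } else {
    f(a, b)
  }
}

grads_zero <- function(params) param_walk(params, NULL, function(a, b) a * 0)
grads_add <- function(g1, g2) param_walk(g1, g2, function(a, b) a + b)
grads_scale <- function(g, s) param_walk(g, NULL, function(a, b) a * s)

adam_init <- function(params) {
  list(m = grads_zero(params), v = grads_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_walk(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_walk(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_walk(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- param_walk(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
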