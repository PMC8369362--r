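# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_dbt <- function(kind, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("dbt_", kind, "_error"), "dbt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

vkey <- function(patient, study, view) paste(patient, study, view, sep = "|")
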