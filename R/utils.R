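# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package route through this,
# so a run-level master seed gives bit-identical results.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive per-component seeds from a master seed by fixed offsets, keeping
# them within the 32-bit signed integer range.
derive_seed <- function(master, offset) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) * 1009 + offset) %% .Machine$integer.max)
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
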