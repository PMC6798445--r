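# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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

# Deterministic per-unit seed derived from a master seed; arithmetic (not a
# draw from the master stream) so that adding units never reshuffles the
# seeds of earlier ones. Always in [1, 2^31 - 2].
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master) %% m) * 69069 + as.double(index) * 104729
  as.integer(s %% (m - 1)) + 1L
}

stop_validation <- function(...) {
  stop(structure(class = c("divimpute_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
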