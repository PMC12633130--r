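# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing stochastic operations route through this so that a seed
# argument fully determines their output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# logit / logistic on probabilities
logit <- function(p) log(p / (1 - p))
logistic <- function(x) 1 / (1 + exp(-x))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic patient identifiers
patient_ids <- function(n, prefix = "P") {
  if (n == 0) return(character(0))
  sprintf("%s%05d", prefix, seq_len(n))
}

stop_hnc <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
warn_hnc <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)
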