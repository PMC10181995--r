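# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

is_power_of_two <- function(w) {
  w >= 1 && abs(w - round(w)) < .Machine$double.eps * 4 &&
    bitwAnd(as.integer(round(w)), as.integer(round(w)) - 1L) == 0L
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      abs(x - round(x)) > 1e-9 || x < min) {
    stop(sprintf("'%s' must be a single integer >= %g", name, min),
         call. = FALSE)
  }
  as.integer(round(x))
}

# Delay a vector by `lag` samples with zero-padded history (streaming
# semantics: a cleared buffer before the first sample).
delay_zero <- function(x, lag) {
  n <- length(x)
  if (lag <= 0L) return(x)
  if (lag >= n) return(numeric(n))
  c(numeric(lag), x[seq_len(n - lag)])
}
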