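#' Streaming pipeline configuration for a mains frequency
#'
#' Standard parameter sets for the integer envelope pipeline: the sampling
#' frequency is chosen so the comb delay is 20 samples for either mains
#' standard, and the 128-sample block window decimates the envelope to about
#' 8 (50 Hz mains) or about 9 (60 Hz mains) output samples per second.
#'
#' | mains | fs (Hz) | comb N | MA window | output rate (Hz) |
#' |-------|---------|--------|-----------|------------------|
#' | 50    | 1000    | 20     | 128       | 7.8125           |
#' | 60    | 1200    | 20     | 128       | 9.375            |
#'
#' @param f_pli Mains frequency: 50 or 60 (Hz).
#' @return An object of class `pipeline_config` with fields `fs`, `ffc_N`,
#'   `ma_window`, `output_rate`.
#' @export
config_for_mains <- function(f_pli) {
  if (!(is.numeric(f_pli) && length(f_pli) == 1L && f_pli %in% c(50, 60))) {
    stop("'f_pli' must be 50 or 60 (Hz)", call. = FALSE)
  }
  fs <- if (f_pli == 50) 1000 else 1200
  pipeline_config(fs = fs, ffc_N = ffc_delay(fs, f_pli), ma_window = 128L)
}

#' @rdname config_for_mains
#' @param fs Sampling frequency in Hz.
#' @param ffc_N Comb delay in samples.
#' @param ma_window Envelope block window in samples; must be a power of 2.
#' @export
pipeline_config <- function(fs, ffc_N, ma_window = 128L) {
  ffc_N <- check_count(ffc_N, "ffc_N", min = 1)
  ma_window <- check_count(ma_window, "ma_window", min = 1)
  if (!is_power_of_two(ma_window)) {
    stop("'ma_window' must be a power of 2 (bit-shift division)",
         call. = FALSE)
  }
  structure(list(fs = fs, ffc_N = ffc_N, ma_window = ma_window,
                 output_rate = fs / ma_window),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> fs = %g Hz, comb N = %d, window = %d, output %.4g Hz\n",
    x$fs, x$ffc_N, x$ma_window, x$output_rate))
  invisible(x)
}

#' Integer-only streaming envelope pipeline
#'
#' Emulates the microcontroller implementation sample by sample, using only
#' integer additions/subtractions, absolute value, and a right bit-shift:
#'
#' 1. comb difference `d = x(k) - x(k - N)` via a ring buffer of `N` codes
#'    (cancels the converter's unipolar offset along with the powerline
#'    harmonics and baseline wander);
#' 2. rectification `|d|`;
#' 3. accumulation of `|d|` over `ma_window` samples; every `ma_window`
#'    inputs one envelope sample `accumulator >> log2(ma_window)` is emitted
#'    (truncating shift; the accumulator is nonnegative so floor equals
#'    truncation).
#'
#' No multiplication or division is ever executed; the returned `ops` tally,
#' counted inside the loop, documents this. The accumulator never exceeds
#' `ma_window * max|d|` (128 * 1023 < 2^17 for a 10-bit converter), well
#' within exact integer range.
#'
#' @param codes Integer vector of ADC codes (nonnegative; `0..1023` for a
#'   10-bit converter).
#' @param cfg A [pipeline_config()].
#' @return A list with `envelope` (an [emg_signal()] of integer envelope
#'   values at `fs / ma_window`) and `ops` (total counts: `additions`,
#'   `multiplications`, `divisions`, `shifts`, `samples_in`).
#' @examples
#' cfg <- config_for_mains(50)
#' out <- stream_process(rep(512L, 512), cfg)
#' out$envelope$samples  # constant input: comb cancels the offset -> 0
#' out$ops$multiplications  # 0
#' @export
stream_process <- function(codes, cfg) {
  if (!inherits(cfg, "pipeline_config")) {
    stop("'cfg' must be a pipeline_config object", call. = FALSE)
  }
  if (any(!is.finite(codes)) || any(abs(codes - round(codes)) > 0)) {
    stop("'codes' must be integer ADC codes", call. = FALSE)
  }
  if (any(codes < 0)) {
    stop("'codes' must be nonnegative (unipolar converter)", call. = FALSE)
  }
  codes <- as.integer(round(codes))
  if (length(codes) < cfg$ma_window) {
    stop(sprintf("need at least one full window (%d samples) of input",
                 cfg$ma_window), call. = FALSE)
  }
  N <- cfg$ffc_N
  W <- cfg$ma_window
  shift <- as.integer(round(log2(W)))
  ring <- integer(N)
  pos <- 1L
  acc <- 0L
  count <- 0L
  out <- integer(length(codes) %/% W)
  emitted <- 0L
  adds <- 0
  for (k in seq_along(codes)) {
    d <- codes[k] - ring[pos]; adds <- adds + 1          # comb difference
    ring[pos] <- codes[k]
    pos <- if (pos == N) 1L else pos + 1L
    if (d < 0L) d <- -d                                  # rectify
    acc <- acc + d; adds <- adds + 1                     # accumulate
    count <- count + 1L
    if (count == W) {
      emitted <- emitted + 1L
      out[emitted] <- bitwShiftR(acc, shift)             # >> log2(W)
      acc <- 0L
      count <- 0L
    }
  }
  list(
    envelope = emg_signal(out[seq_len(emitted)], cfg$fs / W),
    ops = list(additions = adds, multiplications = 0L, divisions = 0L,
               shifts = emitted, samples_in = length(codes))
  )
}
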