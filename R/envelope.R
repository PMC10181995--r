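#' Linear-envelope configuration
#'
#' The EMG linear envelope (EMG-LE) is obtained by full-wave rectification
#' followed by moving-average low-pass filtering. Two variants are supported:
#'
#' * `sliding`: a causal moving average at the input rate; one output per
#'   input sample. The offline analysis setting (window 88 at 1 kHz gives a
#'   cutoff of about 5 Hz).
#' * `block`: non-overlapping windows, one output per window, decimating the
#'   rate to `fs / window`. Requires a power-of-2 window so that on integer
#'   hardware the division by the window length reduces to a right bit-shift
#'   (window 128 at 1 kHz gives about 7.8 envelope samples per second).
#'
#' @param window Window length in samples; positive integer.
#' @param mode `"sliding"` (default) or `"block"`.
#'
#' @return An object of class `envelope_config`.
#' @seealso [linear_envelope()], [ma_cutoff_hz()]
#' @examples
#' envelope_config(88)
#' envelope_config(128, mode = "block")
#' @export
envelope_config <- function(window, mode = c("sliding", "block")) {
  window <- check_count(window, "window", min = 1)
  mode <- match.arg(mode)
  if (mode == "block" && !is_power_of_two(window)) {
    stop("block mode requires 'window' to be a power of 2 (bit-shift division)",
         call. = FALSE)
  }
  structure(list(window = window, mode = mode), class = "envelope_config")
}

#' Full-wave rectification
#'
#' Elementwise absolute value; the first stage of linear-envelope extraction.
#'
#' @param x An [emg_signal()].
#' @return An `emg_signal` with the same sampling frequency.
#' @export
rectify <- function(x) {
  emg_signal(abs(sig_samples(x)), x$fs)
}

#' Causal moving average
#'
#' Sliding mean over the last `window` samples with zero-padded history, so
#' output length equals input length and the first `window - 1` outputs
#' average in leading zeros (streaming semantics).
#'
#' @param x An [emg_signal()].
#' @param window Window length in samples.
#' @return An `emg_signal` at the input rate.
#' @export
moving_average <- function(x, window) {
  s <- sig_samples(x)
  w <- check_count(window, "window", min = 1)
  cs <- cumsum(s)
  y <- (cs - delay_zero(cs, w)) / w
  emg_signal(y, x$fs)
}

#' -3 dB cutoff of a moving-average filter
#'
#' A `W`-sample moving average has magnitude response
#' `|sin(pi W f / fs) / (W sin(pi f / fs))|` (a periodic sinc). The cutoff is
#' the smallest positive frequency where this drops to `1/sqrt(2)`, found by
#' bracketed root search between DC and the first response null `fs / W`.
#' An 88-sample window at 1 kHz gives about 5.03 Hz - the usual "5 Hz"
#' envelope smoothing; a 128-sample window gives about 3.5 Hz.
#'
#' @param window Window length in samples; at least 2 (a 1-sample average is
#'   all-pass and has no cutoff).
#' @param fs Sampling frequency in Hz.
#' @return The cutoff frequency in Hz (root located to well below 1e-6 Hz).
#' @examples
#' ma_cutoff_hz(88, 1000)   # ~5.03
#' ma_cutoff_hz(2, 1000)    # exactly fs/4
#' @export
ma_cutoff_hz <- function(window, fs) {
  w <- check_count(window, "window", min = 1)
  if (w < 2L) {
    stop("a 1-sample moving average is all-pass: no -3 dB cutoff exists",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  gain <- function(f) {
    abs(sin(pi * w * f / fs) / (w * sin(pi * f / fs))) - 1 / sqrt(2)
  }
  # gain(0+) = 1 - 1/sqrt(2) > 0; the response first reaches zero at fs/w
  upper <- fs / w * (1 - 1e-9)
  stats::uniroot(gain, lower = fs * 1e-12, upper = upper,
                 tol = 1e-10 * fs)$root
}

#' EMG linear envelope
#'
#' Rectify then smooth. In `sliding` mode the moving average runs at the input
#' rate; in `block` mode each non-overlapping window of `window` rectified
#' samples is averaged into one output sample and the sampling frequency drops
#' to `fs / window` (any trailing partial window is dropped). The input is
#' expected to be zero-mean (e.g. comb-filtered upstream); this is documented,
#' not enforced, since rectification of a biased signal simply produces a
#' biased envelope.
#'
#' @param x An [emg_signal()].
#' @param cfg An [envelope_config()].
#' @return An `emg_signal`; in block mode with `fs / window` sampling rate.
#' @examples
#' fs <- 1000
#' x <- emg_signal(sin(2 * pi * 100 * (0:4999) / fs), fs)
#' le <- linear_envelope(x, envelope_config(88))
#' mean(le$samples[1000:5000])  # ~2/pi, the mean of |sin|
#' @export
linear_envelope <- function(x, cfg) {
  if (!inherits(cfg, "envelope_config")) {
    stop("'cfg' must be an envelope_config object", call. = FALSE)
  }
  r <- rectify(x)
  if (cfg$mode == "sliding") {
    return(moving_average(r, cfg$window))
  }
  w <- cfg$window
  n_blocks <- length(r$samples) %/% w
  if (n_blocks < 1L) {
    stop(sprintf("input shorter than one block (%d samples)", w),
         call. = FALSE)
  }
  m <- matrix(r$samples[seq_len(n_blocks * w)], nrow = w)
  emg_signal(colMeans(m), x$fs / w)
}
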