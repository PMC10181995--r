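#' Feed-forward comb filter parameters
#'
#' A feed-forward comb (FFC) filter computes `y(k) = x(k) + alpha * x(k - N)`:
#' the input plus a scaled copy of itself delayed by `N` samples. With
#' `alpha = -1` the amplitude response has nulls at every integer multiple of
#' `fs / N`, including DC, which makes a single subtraction cancel a powerline
#' fundamental and all of its harmonics while also removing offset and
#' baseline wander.
#'
#' @param N Delay in samples; positive integer. For powerline cancellation set
#'   `N = fs / f_pli` (see [ffc_delay()]).
#' @param alpha Real filter coefficient. The canonical values are `-1`
#'   (nulls at multiples of `fs/N`) and `+1` (nulls at odd multiples of
#'   `fs/(2N)`); [ffc_apply()] accepts any real `alpha`, the response helpers
#'   only `+/-1`.
#' @param fs Sampling frequency in Hz.
#'
#' @return An object of class `ffc_params`.
#' @seealso [ffc_apply()], [ffc_response()], [ffc_nulls()], [ffc_cutoffs()]
#' @examples
#' ffc_params(N = 20, alpha = -1, fs = 1000)
#' @export
ffc_params <- function(N, alpha = -1, fs) {
  N <- check_count(N, "N", min = 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    stop("'alpha' must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(N = N, alpha = as.double(alpha), fs = as.double(fs)),
            class = "ffc_params")
}

#' @export
print.ffc_params <- function(x, ...) {
  cat(sprintf("<ffc_params> N = %d, alpha = %g, fs = %g Hz\n",
              x$N, x$alpha, x$fs))
  if (x$alpha == -1) {
    cat(sprintf("  nulls every %g Hz (incl. DC); first -3 dB cutoff %g Hz\n",
                x$fs / x$N, x$fs / (4 * x$N)))
  }
  invisible(x)
}

#' Comb delay for powerline cancellation
#'
#' Returns the delay `N = fs / f_pli` that places the nulls of an
#' `alpha = -1` comb filter on the powerline fundamental and every harmonic.
#' The ratio must be an exact integer: a rounded `N` shifts the nulls off the
#' interference harmonics and silently degrades cancellation, so a non-integer
#' ratio is an error rather than a rounding.
#'
#' @param fs Sampling frequency in Hz.
#' @param f_pli Powerline fundamental in Hz (50 or 60 in practice).
#'
#' @return The delay `N` as an integer.
#' @examples
#' ffc_delay(1000, 50)  # 20
#' ffc_delay(1200, 60)  # 20
#' @export
ffc_delay <- function(fs, f_pli) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.numeric(f_pli) || length(f_pli) != 1L || f_pli <= 0) {
    stop("'f_pli' must be a single positive number (Hz)", call. = FALSE)
  }
  ratio <- fs / f_pli
  if (abs(ratio - round(ratio)) > 1e-9) {
    lo <- floor(ratio) * f_pli
    hi <- ceiling(ratio) * f_pli
    stop(sprintf(
      paste0("fs/f_pli = %g is not an integer; the comb nulls would miss the ",
             "powerline harmonics. Nearest admissible sampling frequencies ",
             "for f_pli = %g Hz are %g Hz or %g Hz."),
      ratio, f_pli, lo, hi), call. = FALSE)
  }
  as.integer(round(ratio))
}

#' Apply a feed-forward comb filter
#'
#' Computes `y(k) = x(k) + alpha * x(k - N)` with zero-padded history: the
#' first `N` output samples see a delayed term of 0, matching a streaming
#' implementation started with a cleared delay buffer. Output length and
#' sampling frequency equal the input's.
#'
#' @param x An [emg_signal()].
#' @param params An [ffc_params()] object.
#'
#' @return The filtered signal as an `emg_signal`.
#' @examples
#' fs <- 1000
#' t <- (0:999) / fs
#' pli <- emg_signal(sin(2 * pi * 50 * t), fs)
#' y <- ffc_apply(pli, ffc_params(20, -1, fs))
#' max(abs(y$samples[21:1000]))  # ~0: 50 Hz sits on a null
#' @export
ffc_apply <- function(x, params) {
  s <- sig_samples(x)
  if (!inherits(params, "ffc_params")) {
    stop("'params' must be an ffc_params object", call. = FALSE)
  }
  y <- s + params$alpha * delay_zero(s, params$N)
  emg_signal(y, x$fs)
}

#' Comb amplitude response at a normalized frequency
#'
#' Closed-form magnitude of the comb frequency response:
#' `2 * |sin(pi * N * f_n)|` for `alpha = -1` and `2 * |cos(pi * N * f_n)|`
#' for `alpha = +1`, where `f_n = f / fs` is the normalized frequency. The
#' peak gain is exactly 2, attained midway between adjacent nulls.
#'
#' @param f_norm Normalized frequency in `[0, 0.5]` (may be a vector).
#' @param N Comb delay in samples.
#' @param alpha Either `-1` or `+1`; the general-`alpha` magnitude response is
#'   out of scope.
#'
#' @return Nonnegative gain(s), at most 2.
#' @examples
#' ffc_response(0.050, 20, -1)   # 0: null at 50 Hz for fs = 1000
#' ffc_response(0.025, 20, -1)   # 2: peak gain
#' ffc_response(0.0125, 20, -1)  # sqrt(2): the -3 dB point
#' @export
ffc_response <- function(f_norm, N, alpha) {
  N <- check_count(N, "N", min = 1)
  if (!(isTRUE(all.equal(alpha, -1)) || isTRUE(all.equal(alpha, 1)))) {
    stop("'alpha' must be -1 or +1 for the closed-form amplitude response",
         call. = FALSE)
  }
  if (any(f_norm < 0 | f_norm > 0.5)) {
    stop("'f_norm' must lie in [0, 0.5]", call. = FALSE)
  }
  if (alpha < 0) 2 * abs(sin(pi * N * f_norm)) else 2 * abs(cos(pi * N * f_norm))
}

#' Null frequencies of a comb filter
#'
#' For `alpha = -1` the nulls are `k * fs / N` (k = 0, 1, ...); for
#' `alpha = +1` they are the odd multiples of `fs / (2N)`. A null exactly at
#' `f_max` is included (comparison tolerance 1e-9 Hz).
#'
#' @param params An [ffc_params()] with `alpha` in `{-1, +1}`.
#' @param f_max Upper frequency bound in Hz; at most `fs / 2`.
#'
#' @return Ordered vector of null frequencies in `[0, f_max]`, in Hz.
#' @examples
#' ffc_nulls(ffc_params(20, -1, 1000), 500)  # 0, 50, ..., 500
#' @export
ffc_nulls <- function(params, f_max) {
  stopifnot(inherits(params, "ffc_params"))
  if (f_max > params$fs / 2 + 1e-9) {
    stop("'f_max' must not exceed the Nyquist frequency fs/2", call. = FALSE)
  }
  tol <- 1e-9
  step <- params$fs / params$N
  if (isTRUE(all.equal(params$alpha, -1))) {
    k <- 0:floor((f_max + tol) / step)
    nulls <- k * step
  } else if (isTRUE(all.equal(params$alpha, 1))) {
    half <- step / 2
    k <- 0:max(0, floor((f_max + tol - half) / step))
    nulls <- half + k * step
    nulls <- nulls[nulls <= f_max + tol]
  } else {
    stop("null frequencies are defined here only for alpha = -1 or +1",
         call. = FALSE)
  }
  nulls[nulls <= f_max + tol]
}

#' -3 dB cutoff frequencies of the alpha = -1 comb filter
#'
#' Solving `|sin(pi * N * f / fs)| = 1 / sqrt(2)` gives the half-power
#' frequencies `(1/4 + k) * fs / N` and `(3/4 + k) * fs / N`: each passband
#' lobe between two nulls is bounded by a cutoff `fs / (4N)` away from either
#' null. For N = 20 at 1 kHz these are 12.5 Hz, 37.5 Hz, 62.5 Hz, ...
#'
#' @param params An [ffc_params()] with `alpha = -1`.
#' @param f_max Upper frequency bound in Hz; at most `fs / 2`.
#'
#' @return Ordered vector of -3 dB frequencies in `[0, f_max]`, in Hz.
#' @examples
#' ffc_cutoffs(ffc_params(20, -1, 1000), 100)  # 12.5 37.5 62.5 87.5
#' @export
ffc_cutoffs <- function(params, f_max) {
  stopifnot(inherits(params, "ffc_params"))
  if (!isTRUE(all.equal(params$alpha, -1))) {
    stop("cutoff frequencies are defined for the alpha = -1 comb filter",
         call. = FALSE)
  }
  if (f_max > params$fs / 2 + 1e-9) {
    stop("'f_max' must not exceed the Nyquist frequency fs/2", call. = FALSE)
  }
  tol <- 1e-9
  step <- params$fs / params$N
  kmax <- ceiling((f_max + tol) / step)
  cand <- sort(c((1 / 4 + 0:kmax) * step, (3 / 4 + 0:kmax) * step))
  cand[cand <= f_max + tol]
}
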