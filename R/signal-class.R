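#' Uniformly sampled single-channel signal
#'
#' The carrier object used throughout the package: an ordered numeric vector of
#' samples together with its sampling frequency. Index `k` (1-based in R)
#' corresponds to time `(k - 1) / fs` seconds; sampling is assumed strictly
#' uniform.
#'
#' @param samples Numeric vector of sample values (volts or dimensionless).
#'   Must have length >= 1 and contain only finite values.
#' @param fs Sampling frequency in Hz; a single finite positive number.
#'
#' @return An object of class `emg_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' x <- emg_signal(sin(2 * pi * 50 * (0:999) / 1000), fs = 1000)
#' x
#' @export
emg_signal <- function(samples, fs) {
  samples <- as.double(samples)
  if (length(samples) < 1L) {
    stop("'samples' must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single finite positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.double(fs)), class = "emg_signal")
}

#' @export
print.emg_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf(
    "<emg_signal> %d samples @ %g Hz (%.3f s)\n", n, x$fs, n / x$fs
  ))
  cat("  range: [", format(min(x$samples), digits = 4), ", ",
      format(max(x$samples), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
length.emg_signal <- function(x) length(x$samples)

#' @export
as.double.emg_signal <- function(x, ...) x$samples

# Internal: accept an emg_signal and return its samples, or fail loudly.
sig_samples <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "emg_signal")) {
    stop(sprintf("'%s' must be an emg_signal (see emg_signal())", arg),
         call. = FALSE)
  }
  x$samples
}

# Internal: check two signals share a sampling rate (exact match expected;
# both sides come from this package's constructors).
check_same_fs <- function(a, b) {
  if (!isTRUE(all.equal(a$fs, b$fs))) {
    stop(sprintf("sampling frequencies differ: %g Hz vs %g Hz", a$fs, b$fs),
         call. = FALSE)
  }
  invisible(TRUE)
}
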