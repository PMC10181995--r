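#' Read a single-channel signal from CSV
#'
#' The canonical interchange format is a plain-text file whose first line is
#' a comment header declaring the sampling rate, `# fs=<Hz>`, followed by one
#' sample value per line. A file without the header is rejected: a signal is
#' meaningless without its sampling frequency.
#'
#' @param path Path to the file.
#' @return An [emg_signal()].
#' @seealso [write_signal()]
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^#\\s*fs\\s*=\\s*([0-9eE.+-]+)\\s*$", header))[[1]]
  if (length(m) < 2L) {
    stop("missing sampling-rate header: first line must be '# fs=<Hz>'",
         call. = FALSE)
  }
  fs <- as.numeric(m[2])
  if (!is.finite(fs) || fs <= 0) {
    stop("invalid sampling rate in header", call. = FALSE)
  }
  samples <- scan(path, what = double(), skip = 1L, quiet = TRUE,
                  comment.char = "#")
  emg_signal(samples, fs)
}

#' Write a single-channel signal to CSV
#'
#' Writes the `# fs=<Hz>` header followed by one sample per line at full
#' double precision (17 significant digits), so a read/write round trip is
#' exact.
#'
#' @param x An [emg_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  s <- sig_samples(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", x$fs), con)
  writeLines(sprintf("%.17g", s), con)
  invisible(path)
}
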