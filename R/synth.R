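#' Powerline-interference specification
#'
#' Describes a harmonic powerline interference (PLI) waveform: a fundamental
#' `f0` plus harmonics, each with a relative amplitude and phase, optionally
#' amplitude-modulated by a slow sinewave. The default profile has harmonics
#' up to `f_max` (500 Hz for 50 Hz mains) with `1/h` amplitude decay and
#' random fixed phases drawn once from the given seed - a generic stand-in
#' for a measured mains spectrum, which is installation-specific.
#'
#' @param f0 Fundamental frequency in Hz (50 or 60 in practice).
#' @param harmonics Data frame with columns `h` (harmonic index), `amp`
#'   (relative amplitude) and `phase` (radians), or `NULL` for the default
#'   `1/h` profile up to `f_max`.
#' @param modulation `NULL` for flat amplitude, or a list with `freq` (Hz)
#'   and `depth` (in `[0, 1)`); the waveform is multiplied by
#'   `1 + depth * sin(2 pi freq t)`. Defaults used by `modulated = TRUE`:
#'   0.5 Hz at depth 0.5.
#' @param f_max Highest harmonic frequency for the default profile, in Hz.
#' @param seed Integer seed for the default random phases.
#' @param modulated Convenience switch: `TRUE` installs the default
#'   modulation when `modulation` is `NULL`.
#' @return An object of class `pli_spec`.
#' @export
pli_spec <- function(f0 = 50, harmonics = NULL, modulation = NULL,
                     f_max = 500, seed = 1, modulated = FALSE) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0) {
    stop("'f0' must be a single positive frequency (Hz)", call. = FALSE)
  }
  if (is.null(harmonics)) {
    hmax <- floor(f_max / f0 + 1e-9)
    if (hmax < 1L) stop("'f_max' below the fundamental", call. = FALSE)
    phases <- with_seed(seed, stats::runif(hmax, 0, 2 * pi))
    harmonics <- data.frame(h = seq_len(hmax), amp = 1 / seq_len(hmax),
                            phase = phases)
  } else {
    harmonics <- as.data.frame(harmonics)
    if (!all(c("h", "amp", "phase") %in% names(harmonics))) {
      stop("'harmonics' needs columns h, amp, phase", call. = FALSE)
    }
  }
  if (modulated && is.null(modulation)) {
    modulation <- list(freq = 0.5, depth = 0.5)
  }
  if (!is.null(modulation)) {
    if (!is.list(modulation) || is.null(modulation$freq) ||
        is.null(modulation$depth)) {
      stop("'modulation' must be NULL or list(freq=, depth=)", call. = FALSE)
    }
    if (modulation$depth < 0 || modulation$depth >= 1) {
      stop("modulation depth must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(list(f0 = f0, harmonics = harmonics, modulation = modulation),
            class = "pli_spec")
}

#' Synthesize powerline interference
#'
#' Sum of `amp_h * sin(2 pi h f0 t + phase_h)` over the configured harmonics,
#' multiplied by `1 + depth * sin(2 pi f_mod t)` when modulation is set.
#'
#' @param duration Length in seconds.
#' @param fs Sampling frequency in Hz; all harmonics must lie below `fs / 2`.
#' @param spec A [pli_spec()] object.
#' @return An `emg_signal`.
#' @export
synth_pli <- function(duration, fs, spec) {
  if (!inherits(spec, "pli_spec")) {
    stop("'spec' must be a pli_spec object", call. = FALSE)
  }
  n <- round(duration * fs)
  if (n < 1) stop("duration * fs must be at least 1 sample", call. = FALSE)
  freqs <- spec$harmonics$h * spec$f0
  if (any(freqs > fs / 2 + 1e-9)) {
    stop(sprintf("harmonic at %g Hz exceeds the Nyquist frequency %g Hz",
                 max(freqs), fs / 2), call. = FALSE)
  }
  t <- (0:(n - 1)) / fs
  y <- numeric(n)
  for (i in seq_len(nrow(spec$harmonics))) {
    y <- y + spec$harmonics$amp[i] *
      sin(2 * pi * freqs[i] * t + spec$harmonics$phase[i])
  }
  if (!is.null(spec$modulation)) {
    y <- y * (1 + spec$modulation$depth *
                sin(2 * pi * spec$modulation$freq * t))
  }
  emg_signal(y, fs)
}

#' Synthesize surrogate surface EMG
#'
#' Band-limited burst-modulated Gaussian noise emulating a forearm sEMG
#' recording: zero-mean white noise shaped to the 20-450 Hz band (4th-order
#' Butterworth applied forward-backward, so zero phase), then multiplied by a
#' burst profile alternating rest (relative level `rest_level`) and
#' contraction plateaus with raised-cosine onsets/offsets. Segment durations
#' are drawn uniformly from `seg_range` seconds and contraction amplitudes
#' from `amp_range`. Deterministic for a given seed.
#'
#' @param duration Length in seconds.
#' @param fs Sampling frequency in Hz; at least 1000 so the 450 Hz band edge
#'   stays below Nyquist.
#' @param seed Integer seed.
#' @param rest_level Relative envelope during rest segments.
#' @param seg_range Min/max segment duration in seconds.
#' @param amp_range Min/max contraction plateau amplitude (relative).
#' @param ramp Raised-cosine transition time between segments, seconds.
#' @return An `emg_signal`.
#' @export
synth_emg <- function(duration, fs, seed, rest_level = 0.05,
                      seg_range = c(0.5, 2), amp_range = c(0.5, 1),
                      ramp = 0.2) {
  if (fs < 1000) {
    stop("'fs' must be >= 1000 Hz: the 20-450 Hz EMG band needs the Nyquist ",
         "frequency above 450 Hz with margin", call. = FALSE)
  }
  n <- round(duration * fs)
  if (n < 1) stop("duration * fs must be at least 1 sample", call. = FALSE)
  with_seed(seed, {
    carrier <- stats::rnorm(n)
    bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
    carrier <- signal::filtfilt(bp, carrier)
    # piecewise-constant activation profile: rest / contraction alternation
    env <- numeric(n)
    pos <- 1L
    active <- FALSE
    while (pos <= n) {
      len <- max(1L, round(stats::runif(1, seg_range[1], seg_range[2]) * fs))
      amp <- if (active) stats::runif(1, amp_range[1], amp_range[2])
             else rest_level
      env[pos:min(n, pos + len - 1L)] <- amp
      pos <- pos + len
      active <- !active
    }
    # Hann-weighted smoothing turns each step into a raised-cosine ramp
    rl <- max(3L, round(ramp * fs))
    h <- 0.5 * (1 - cos(2 * pi * seq_len(rl) / (rl + 1)))
    h <- h / sum(h)
    padded <- c(rep(env[1], rl), env, rep(env[n], rl))
    env <- stats::filter(padded, h, sides = 2)[(rl + 1):(rl + n)]
    emg_signal(carrier * as.numeric(env), fs)
  })
}

#' Synthesize a motion-artifact surrogate
#'
#' Low-frequency baseline wander: zero-mean Gaussian noise low-pass filtered
#' at `cutoff` Hz (4th-order Butterworth, forward-backward). The default 4 Hz
#' concentrates the energy well below a 12.5 Hz comb cutoff, the regime in
#' which electrode-motion baseline disturbances mostly live; cutoffs up to
#' 30 Hz are allowed for stress testing (with a warning above 30 Hz).
#'
#' @param duration Length in seconds.
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed.
#' @param cutoff Low-pass cutoff in Hz; below `fs / 2`.
#' @return An `emg_signal`.
#' @export
synth_artifact <- function(duration, fs, seed, cutoff = 4) {
  if (cutoff >= fs / 2) {
    stop("'cutoff' must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  if (cutoff > 30) {
    warning("cutoff above 30 Hz: outside the usual motion-artifact band",
            call. = FALSE)
  }
  n <- round(duration * fs)
  if (n < 1) stop("duration * fs must be at least 1 sample", call. = FALSE)
  with_seed(seed, {
    noise <- stats::rnorm(n)
    lp <- signal::butter(4, cutoff / (fs / 2), type = "low")
    emg_signal(signal::filtfilt(lp, noise), fs)
  })
}

#' Mix noise into a signal at an exact SNR
#'
#' Scales the noise so that the linear power ratio
#' `mean(signal^2) / mean((s * noise)^2)` equals `snr` exactly, and returns
#' the mixture. SNR is a mean-square power ratio over the whole record.
#' Ratios outside `[0.05, 10]` - the usual corruption-sweep range - are
#' allowed with a warning.
#'
#' @param signal,noise [emg_signal()]s of equal length and sampling rate.
#' @param snr Linear power ratio, > 0.
#' @return A list with `mixed` (the corrupted `emg_signal`) and `scale`
#'   (the factor applied to the noise).
#' @export
mix_at_snr <- function(signal, noise, snr) {
  s <- sig_samples(signal)
  v <- sig_samples(noise)
  check_same_fs(signal, noise)
  if (length(s) != length(v)) {
    stop("'signal' and 'noise' must have equal length", call. = FALSE)
  }
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0) {
    stop("'snr' must be a single positive number", call. = FALSE)
  }
  if (snr < 0.05 || snr > 10) {
    warning("snr outside the protocol range [0.05, 10]", call. = FALSE)
  }
  p_noise <- mean(v^2)
  if (p_noise == 0) {
    stop("noise has zero power; SNR scaling is undefined", call. = FALSE)
  }
  scale <- sqrt(mean(s^2) / (snr * p_noise))
  list(mixed = emg_signal(s + scale * v, signal$fs), scale = scale)
}

#' Emulate a unipolar analog-to-digital converter
#'
#' Quantizes `x + offset` to integer codes `0 ... 2^bits - 1` with step
#' `full_scale / 2^bits`, clipping out-of-range values (clipping is counted,
#' not fatal). Models the unipolar 10-bit converters common on
#' microcontroller boards; the mid-scale offset recenters a bipolar signal.
#'
#' @param x An [emg_signal()] in volts.
#' @param bits Resolution in bits.
#' @param full_scale Full-scale input range in volts.
#' @param offset Offset added before quantization, volts.
#' @return A list with `codes` (integer vector), `fs`, `clipped` (number of
#'   clipped samples), and `lsb` (the quantization step in volts).
#' @export
adc_emulate <- function(x, bits = 10, full_scale, offset = 0) {
  s <- sig_samples(x)
  bits <- check_count(bits, "bits", min = 1)
  if (!is.numeric(full_scale) || full_scale <= 0) {
    stop("'full_scale' must be positive (volts)", call. = FALSE)
  }
  levels <- 2^bits
  lsb <- full_scale / levels
  raw <- floor((s + offset) / lsb)
  clipped <- sum(raw < 0 | raw > levels - 1)
  codes <- pmin(pmax(raw, 0), levels - 1)
  list(codes = as.integer(codes), fs = x$fs, clipped = as.integer(clipped),
       lsb = lsb)
}
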