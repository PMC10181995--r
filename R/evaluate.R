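#' Lag of best cross-correlation alignment
#'
#' Locates the maximum of the full (all-lags) cross-correlation between a
#' reference and a test signal after mean removal, and returns the signed lag
#' in samples. A positive lag means the test signal is delayed relative to
#' the reference: `test[k + lag]` lines up with `ref[k]`.
#'
#' @param ref,test [emg_signal()]s at the same sampling rate; both must be
#'   non-constant (the correlation of a constant series is undefined).
#' @return Integer lag in samples.
#' @examples
#' fs <- 100
#' x <- emg_signal(sin(2 * pi * 3 * (0:499) / fs) * exp(-(0:499) / 200), fs)
#' y <- emg_signal(c(numeric(7), x$samples[1:493]), fs)
#' align_lag(x, y)  # 7
#' @export
align_lag <- function(ref, test) {
  a <- sig_samples(ref)
  b <- sig_samples(test)
  check_same_fs(ref, test)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("cross-correlation alignment is undefined for constant signals",
         call. = FALSE)
  }
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  n <- max(length(a0), length(b0))
  L <- stats::nextn(2L * n, 2)
  A <- stats::fft(c(a0, numeric(L - length(a0))))
  B <- stats::fft(c(b0, numeric(L - length(b0))))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / L
  # cc[m + 1] = sum_k a0[k] * b0[k - m] (circular in L, so negative lags sit
  # at the tail); padding to >= 2n makes lags -(n-1) ... (n-1) linear.
  # b = a delayed by d peaks at m = -d.
  m <- -(n - 1L):(n - 1L)
  idx <- ifelse(m >= 0L, m + 1L, L + m + 1L)
  -m[which.max(cc[idx])]
}

#' Pearson correlation of two signals
#'
#' Standard product-moment correlation of the overlapping samples. Inputs are
#' expected to be re-aligned (see [align_lag()]) and trimmed of filter
#' transients before calling; [envelope_fidelity()] wraps the full protocol.
#'
#' @param a,b [emg_signal()]s or numeric vectors of equal length >= 2; both
#'   non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  va <- if (inherits(a, "emg_signal")) a$samples else as.double(a)
  vb <- if (inherits(b, "emg_signal")) b$samples else as.double(b)
  if (length(va) != length(vb) || length(va) < 2L) {
    stop("'a' and 'b' must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("Pearson correlation is undefined for constant series",
         call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Envelope-recovery fidelity
#'
#' The core evaluation measure: compute the linear envelopes of a clean
#' reference signal and a processed (noisy or filtered) signal, discard the
#' start-up transient, re-align by the peak of the full cross-correlation,
#' and return the Pearson correlation of the overlapping region.
#'
#' @param clean,processed [emg_signal()]s of equal length and rate.
#' @param cfg An [envelope_config()]; default 88-sample sliding window, the
#'   offline analysis setting.
#' @param transient Samples to discard from the start of both envelopes
#'   before correlating; default `cfg$window + 1000`. When the processed
#'   signal went through a filter with memory deeper than the envelope
#'   window, pass `max(filter memory, window) + 1000`.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
envelope_fidelity <- function(clean, processed,
                              cfg = envelope_config(88),
                              transient = cfg$window + 1000L) {
  check_same_fs(clean, processed)
  if (length(clean$samples) != length(processed$samples)) {
    stop("'clean' and 'processed' must have equal length", call. = FALSE)
  }
  e_ref <- linear_envelope(clean, cfg)
  e_test <- linear_envelope(processed, cfg)
  n <- length(e_ref$samples)
  transient <- max(0L, as.integer(round(transient)))
  if (n - transient < 100L) {
    stop("signal too short after transient removal", call. = FALSE)
  }
  keep <- (transient + 1L):n
  r <- emg_signal(e_ref$samples[keep], e_ref$fs)
  s <- emg_signal(e_test$samples[keep], e_test$fs)
  lag <- align_lag(r, s)
  m <- length(keep)
  if (abs(lag) >= m - 1L) {
    stop("alignment lag exhausts the overlap", call. = FALSE)
  }
  if (lag >= 0L) {
    pearson_r(r$samples[seq_len(m - lag)], s$samples[(1L + lag):m])
  } else {
    pearson_r(r$samples[(1L - lag):m], s$samples[seq_len(m + lag)])
  }
}

#' Correlation gain
#'
#' Ratio of the filtered-envelope correlation to the noisy-envelope
#' correlation against the true envelope: how much of the envelope fidelity
#' the filter restores. A gain above 1 means filtering helped.
#'
#' @param r_filtered,r_noisy Correlations; `r_noisy` must be nonzero.
#' @return `r_filtered / r_noisy`.
#' @export
correlation_gain <- function(r_filtered, r_noisy) {
  if (any(r_noisy == 0)) {
    stop("correlation gain is undefined when the noisy correlation is 0",
         call. = FALSE)
  }
  r_filtered / r_noisy
}

# Filter memory in samples, for transient sizing inside the sweep.
filter_memory <- function(algorithm, fs, f_pli, nf_dxn, fft_block) {
  switch(algorithm,
         none = 0L,
         ffc = as.integer(fs / f_pli),
         dxn = as.integer(fs / f_pli) * (nf_dxn - 1L) + 1L,
         fft = as.integer(fft_block))
}

#' SNR-sweep corruption experiment
#'
#' The full evaluation protocol: for every seed, generate a clean surrogate
#' EMG record; for every corruption kind, synthesize the corresponding noise
#' (flat powerline interference, amplitude-modulated powerline interference,
#' or low-frequency motion artifact); mix at each SNR on the grid; filter
#' with each algorithm; and score the recovered envelope against the clean
#' envelope via [envelope_fidelity()]. Noise is generated from a seed offset
#' by 1000 from the EMG seed so the artifact surrogate never shares random
#' draws with the EMG carrier.
#'
#' @param snr Numeric vector of linear SNR values (sorted internally). The
#'   default grid `{0.05, 0.1, 0.2, 0.5, 1, 2, 5, 7, 10}` spans the usual
#'   corruption range.
#' @param corruptions Subset of `"pli-flat"`, `"pli-modulated"`,
#'   `"artifact"`.
#' @param algorithms Subset of `"none"` (identity), `"ffc"`, `"dxn"`,
#'   `"fft"`.
#' @param seeds Integer vector of seeds; each contributes one replicate per
#'   grid point.
#' @param duration Record length in seconds.
#' @param fs Sampling frequency in Hz.
#' @param f_pli Powerline fundamental in Hz; `fs / f_pli` must be integer.
#' @param window Envelope window in samples (sliding mode).
#' @param nf_dxn Tap count for the D-spaced comb baseline.
#' @param artifact_cutoff Low-pass cutoff of the artifact surrogate, Hz.
#' @return A data frame of class `sweep_result` with columns `snr`,
#'   `corruption`, `algorithm`, `seed`, `r_noisy`, `r_filtered`; one row per
#'   grid point x corruption x algorithm x seed.
#' @examples
#' \donttest{
#' res <- run_sweep(snr = c(0.05, 1, 10), corruptions = "pli-flat",
#'                  algorithms = "ffc", seeds = 1:2, duration = 10)
#' aggregate(r_filtered ~ snr, res, min)
#' }
#' @export
run_sweep <- function(snr = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 7, 10),
                      corruptions = c("pli-flat", "pli-modulated", "artifact"),
                      algorithms = c("none", "ffc", "dxn", "fft"),
                      seeds = 1:5,
                      duration = 30, fs = 1000, f_pli = 50,
                      window = 88, nf_dxn = 17, artifact_cutoff = 4) {
  corruptions <- match.arg(corruptions, several.ok = TRUE)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  snr <- sort(snr)
  N <- ffc_delay(fs, f_pli)
  cfg <- envelope_config(window)
  ffc_p <- ffc_params(N, -1, fs)
  dxn_p <- dxn_params(N, nf_dxn)
  fft_block <- ffc_delay(fs, 25)          # 25 Hz resolution
  fft_p <- fft_filter_params(fft_block, fft_pli_bins(fs, fft_block, f_pli))

  rows <- list()
  for (seed in seeds) {
    clean <- synth_emg(duration, fs, seed)
    for (kind in corruptions) {
      noise_seed <- seed + 1000L
      noise <- switch(
        kind,
        "pli-flat" = synth_pli(duration, fs,
                               pli_spec(f0 = f_pli, f_max = 500,
                                        seed = noise_seed)),
        "pli-modulated" = synth_pli(duration, fs,
                                    pli_spec(f0 = f_pli, f_max = 500,
                                             seed = noise_seed,
                                             modulated = TRUE)),
        "artifact" = synth_artifact(duration, fs, noise_seed,
                                    cutoff = artifact_cutoff)
      )
      for (s in snr) {
        mixed <- mix_at_snr(clean, noise, s)$mixed
        r_noisy <- envelope_fidelity(clean, mixed, cfg,
                                     transient = window + 1000L)
        for (alg in algorithms) {
          filtered <- switch(alg,
                             none = mixed,
                             ffc = ffc_apply(mixed, ffc_p),
                             dxn = filter_dxn(mixed, dxn_p),
                             fft = fft_block_filter(mixed, fft_p))
          tr <- max(filter_memory(alg, fs, f_pli, nf_dxn, fft_block),
                    window) + 1000L
          r_filt <- envelope_fidelity(clean, filtered, cfg, transient = tr)
          rows[[length(rows) + 1L]] <- data.frame(
            snr = s, corruption = kind, algorithm = alg, seed = seed,
            r_noisy = r_noisy, r_filtered = r_filt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}
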