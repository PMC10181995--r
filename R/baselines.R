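#' Parameters of the D-spaced integer comb baseline (FilterDxN)
#'
#' An integer-coefficient, high quality-factor comb used as a comparison
#' denoiser: the filter subtracts from the current sample the mean of `Nf`
#' samples spaced `D` apart,
#' `y(k) = x(k) - (1/Nf) * sum_{i=0}^{Nf-1} x(k - i*D)`.
#' With `D = fs / f_pli` the comb-spaced mean passes exactly the components at
#' multiples of `fs / D` (where all taps are in phase), so the subtraction
#' places zeros at DC and at every powerline harmonic. The reference setting
#' used for comparison is D = 20, Nf = 17 at 1 kHz ("Filter20x17").
#'
#' @param D Tooth spacing in samples (`fs / f_pli`); positive integer.
#' @param Nf Number of comb-spaced taps; integer >= 2.
#' @return An object of class `dxn_params`.
#' @export
dxn_params <- function(D, Nf) {
  D <- check_count(D, "D", min = 1)
  Nf <- check_count(Nf, "Nf", min = 2)
  structure(list(D = D, Nf = Nf), class = "dxn_params")
}

#' Apply the D-spaced comb baseline filter
#'
#' Zero-padded history; the transient spans `D * (Nf - 1)` samples (the
#' deepest tap). Zeros of the response fall at all multiples of `fs / D`,
#' including DC.
#'
#' @param x An [emg_signal()].
#' @param p A [dxn_params()] object.
#' @return The filtered signal as an `emg_signal`.
#' @export
filter_dxn <- function(x, p) {
  s <- sig_samples(x)
  if (!inherits(p, "dxn_params")) {
    stop("'p' must be a dxn_params object", call. = FALSE)
  }
  m <- numeric(length(s))
  for (i in 0:(p$Nf - 1L)) {
    m <- m + delay_zero(s, i * p$D)
  }
  emg_signal(s - m / p$Nf, x$fs)
}

#' Parameters of the FFT block filter
#'
#' The FFT-based comparison denoiser transforms consecutive non-overlapping
#' blocks, zeroes a fixed set of spectral bins (with their conjugate-symmetric
#' partners, so the output stays real), and inverse-transforms. The block
#' length sets the frequency resolution `fs / block`; a 40-sample block at
#' 1 kHz gives 25 Hz resolution, the coarsest grid on which both the 50 Hz
#' harmonics and a 0-25 Hz low-frequency band land exactly on bins.
#'
#' @param block Samples per transform; integer >= 2.
#' @param zero_bins Integer bin indices in `0:(block/2)` to cancel (0 = DC).
#' @return An object of class `fft_filter_params`.
#' @seealso [fft_pli_bins()] for the default powerline + low-frequency set.
#' @export
fft_filter_params <- function(block, zero_bins) {
  block <- check_count(block, "block", min = 2)
  zero_bins <- vapply(zero_bins, check_count, integer(1), name = "zero_bins",
                      min = 0)
  zero_bins <- sort(unique(as.integer(zero_bins)))
  if (any(zero_bins > block %/% 2)) {
    stop("'zero_bins' must lie in 0:(block/2)", call. = FALSE)
  }
  structure(list(block = block, zero_bins = zero_bins),
            class = "fft_filter_params")
}

#' Default cancelled-bin set for powerline and motion-artifact removal
#'
#' Bins covering DC through `low_cut` Hz inclusive (motion artifacts and
#' baseline wander) plus the bin of every harmonic of `f_pli` up to Nyquist.
#' Harmonics must fall exactly on bins, i.e. `f_pli` must be a multiple of
#' the resolution `fs / block`.
#'
#' @param fs Sampling frequency in Hz.
#' @param block Samples per transform.
#' @param f_pli Powerline fundamental in Hz.
#' @param low_cut Upper edge of the low-frequency cancellation band in Hz.
#' @return Integer vector of bin indices. For `fs = 1000`, `block = 40`:
#'   `{0, 1, 2, 4, 6, ..., 20}`, i.e. 0-25 Hz and 50, 100, ..., 500 Hz.
#' @export
fft_pli_bins <- function(fs, block, f_pli = 50, low_cut = 25) {
  block <- check_count(block, "block", min = 2)
  res <- fs / block
  ratio <- f_pli / res
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf(
      "f_pli = %g Hz does not fall on a bin (resolution %g Hz)", f_pli, res),
      call. = FALSE)
  }
  low <- 0:floor(low_cut / res + 1e-9)
  harm <- round(ratio) * seq_len(floor((fs / 2) / f_pli + 1e-9))
  sort(unique(c(low, harm[harm <= block %/% 2])))
}

#' Apply the FFT block filter
#'
#' Processes consecutive non-overlapping blocks: forward FFT, cancellation of
#' the configured bins and their conjugate partners, inverse FFT. A trailing
#' partial block shorter than `block` is passed through unfiltered with a
#' warning. The filter is exactly linear and its output is real to machine
#' precision.
#'
#' @param x An [emg_signal()] with at least `block` samples.
#' @param p An [fft_filter_params()] object.
#' @return The filtered signal as an `emg_signal`.
#' @export
fft_block_filter <- function(x, p) {
  s <- sig_samples(x)
  if (!inherits(p, "fft_filter_params")) {
    stop("'p' must be an fft_filter_params object", call. = FALSE)
  }
  B <- p$block
  n <- length(s)
  if (n < B) {
    stop(sprintf("input (%d samples) shorter than one block (%d)", n, B),
         call. = FALSE)
  }
  idx <- p$zero_bins + 1L
  partners <- B + 1L - p$zero_bins[p$zero_bins > 0L & p$zero_bins < B / 2]
  kill <- unique(c(idx, partners))
  n_blocks <- n %/% B
  y <- s
  for (b in seq_len(n_blocks)) {
    at <- ((b - 1L) * B + 1L):(b * B)
    X <- stats::fft(s[at])
    X[kill] <- 0
    y[at] <- Re(stats::fft(X, inverse = TRUE)) / B
  }
  rem <- n - n_blocks * B
  if (rem > 0L) {
    warning(sprintf(
      "trailing partial block of %d samples passed through unfiltered", rem),
      call. = FALSE)
  }
  emg_signal(y, x$fs)
}

#' Arithmetic and memory cost per algorithm
#'
#' Analytic operation counts for the denoising filters, in the accounting
#' convention used when comparing streaming implementations:
#'
#' * `ffc`: 1 addition per output sample (the single subtraction), no
#'   multiplications or divisions, `N` stored input samples.
#' * `dxn`: `Nf` additions (`Nf - 1` for the comb-spaced sum plus the final
#'   subtraction), 1 division, and `D * (Nf - 1) + 1` stored samples (the
#'   deepest tap plus the current sample). For D = 20, Nf = 17: 17 additions,
#'   1 division, 321 samples.
#' * `fft`: a lower bound of `floor((block/2) * log2(block))` complex
#'   butterfly additions and as many multiplications for one block transform
#'   (106 for a 40-sample block), with `block` stored samples. These counts
#'   are per transform, the convention in which block-FFT costs are usually
#'   quoted, and grow superlinearly with block size.
#' * `ma-envelope`: a sliding moving average needs 2 additions (add the new
#'   sample, subtract the oldest) and 1 division per output, storing `window`
#'   samples; a block average with a power-of-2 window needs 1 addition and no
#'   division (right bit-shift), storing only the accumulator.
#'
#' @param algorithm One of `"ffc"`, `"dxn"`, `"fft"`, `"ma-envelope"`.
#' @param params The matching parameter object ([ffc_params()],
#'   [dxn_params()], [fft_filter_params()], or [envelope_config()]).
#' @return An object of class `resource_profile` with integer fields
#'   `additions`, `multiplications`, `divisions`, `memory`.
#' @examples
#' resource_profile("ffc", ffc_params(20, -1, 1000))
#' resource_profile("dxn", dxn_params(20, 17))
#' @export
resource_profile <- function(algorithm = c("ffc", "dxn", "fft", "ma-envelope"),
                             params) {
  algorithm <- match.arg(algorithm)
  prof <- switch(
    algorithm,
    ffc = {
      stopifnot(inherits(params, "ffc_params"))
      list(additions = 1L, multiplications = 0L, divisions = 0L,
           memory = params$N)
    },
    dxn = {
      stopifnot(inherits(params, "dxn_params"))
      list(additions = params$Nf, multiplications = 0L, divisions = 1L,
           memory = params$D * (params$Nf - 1L) + 1L)
    },
    fft = {
      stopifnot(inherits(params, "fft_filter_params"))
      ops <- as.integer(floor((params$block / 2) * log2(params$block)))
      list(additions = ops, multiplications = ops, divisions = 0L,
           memory = params$block)
    },
    `ma-envelope` = {
      stopifnot(inherits(params, "envelope_config"))
      if (params$mode == "sliding") {
        list(additions = 2L, multiplications = 0L, divisions = 1L,
             memory = params$window)
      } else {
        list(additions = 1L, multiplications = 0L, divisions = 0L,
             memory = 1L)
      }
    }
  )
  structure(c(prof, list(algorithm = algorithm)), class = "resource_profile")
}

#' @export
print.resource_profile <- function(x, ...) {
  cat(sprintf(
    "<resource_profile> %s: %d add, %d mult, %d div per sample; %d samples stored\n",
    x$algorithm, x$additions, x$multiplications, x$divisions, x$memory))
  invisible(x)
}

#' Instrumented scalar filter run
#'
#' Runs the `ffc` or `dxn` filter as an explicit per-sample loop over a ring
#' buffer, tallying every addition/subtraction, multiplication and division
#' actually executed, and recording the buffer size. Used to confirm the
#' analytic [resource_profile()] counts and to cross-check the vectorized
#' implementations; not intended for long signals.
#'
#' @param algorithm `"ffc"` or `"dxn"`.
#' @param x An [emg_signal()].
#' @param params [ffc_params()] (with `alpha = -1`) or [dxn_params()].
#' @return A list with `signal` (the filtered `emg_signal`) and `ops`
#'   (per-output-sample counts: `additions`, `multiplications`, `divisions`,
#'   `memory`).
#' @export
instrument_filter <- function(algorithm = c("ffc", "dxn"), x, params) {
  algorithm <- match.arg(algorithm)
  s <- sig_samples(x)
  n <- length(s)
  adds <- 0; mults <- 0; divs <- 0
  if (algorithm == "ffc") {
    stopifnot(inherits(params, "ffc_params"))
    if (!isTRUE(all.equal(params$alpha, -1))) {
      stop("instrumented FFC covers the multiplication-free alpha = -1 filter",
           call. = FALSE)
    }
    N <- params$N
    ring <- numeric(N)
    pos <- 1L
    y <- numeric(n)
    for (k in seq_len(n)) {
      y[k] <- s[k] - ring[pos]; adds <- adds + 1
      ring[pos] <- s[k]
      pos <- if (pos == N) 1L else pos + 1L
    }
    mem <- N
  } else {
    stopifnot(inherits(params, "dxn_params"))
    D <- params$D; Nf <- params$Nf
    len <- D * (Nf - 1L) + 1L       # current sample plus deepest tap
    ring <- numeric(len)
    pos <- 1L
    y <- numeric(n)
    for (k in seq_len(n)) {
      ring[pos] <- s[k]
      acc <- ring[pos]
      for (i in seq_len(Nf - 1L)) {
        at <- pos - i * D
        at <- ((at - 1L) %% len) + 1L
        acc <- acc + ring[at]; adds <- adds + 1
      }
      y[k] <- s[k] - acc / Nf; adds <- adds + 1; divs <- divs + 1
      pos <- if (pos == len) 1L else pos + 1L
    }
    mem <- len
  }
  list(
    signal = emg_signal(y, x$fs),
    ops = list(additions = adds / n, multiplications = mults / n,
               divisions = divs / n, memory = mem)
  )
}
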