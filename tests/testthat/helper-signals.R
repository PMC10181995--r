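# Shared fixture builders: everything generated in code at test time.

white_sig <- function(n, fs = 1000, seed = 42) {
  set.seed(seed)
  emg_signal(rnorm(n), fs)
}

tone <- function(freq, fs = 1000, n = 5000, amp = 1, phase = 0) {
  emg_signal(amp * sin(2 * pi * freq * (0:(n - 1)) / fs + phase), fs)
}

# Independent brute-force oracle for the two-tap comb: explicit per-sample
# loop over the difference equation, zero-padded history.
comb_loop_oracle <- function(x, N, alpha) {
  n <- length(x)
  y <- numeric(n)
  for (k in seq_len(n)) {
    past <- if (k - N >= 1) x[k - N] else 0
    y[k] <- x[k] + alpha * past
  }
  y
}

# Brute-force windowed mean with zero-padded history.
ma_loop_oracle <- function(x, w) {
  n <- length(x)
  y <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1, k - w + 1)
    y[k] <- (sum(x[lo:k])) / w
  }
  y
}

# Brute-force D-spaced comb mean subtraction.
dxn_loop_oracle <- function(x, D, Nf) {
  n <- length(x)
  y <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0
    for (i in 0:(Nf - 1)) {
      idx <- k - i * D
      acc <- acc + if (idx >= 1) x[idx] else 0
    }
    y[k] <- x[k] - acc / Nf
  }
  y
}

# Least-squares amplitude of a known-frequency sinusoid over a window whose
# length is an exact number of cycles (frequency on a DFT bin), so the
# projection is leakage-free.
projected_amplitude <- function(y, f, fs) {
  n <- length(y)
  k <- 0:(n - 1)
  2 * Mod(sum(y * exp(-2i * pi * f * k / fs))) / n
}
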