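test_that("generators are pure functions of their seed", {
  a <- synth_emg(2, 1000, 7)
  b <- synth_emg(2, 1000, 7)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, synth_emg(2, 1000, 8)$samples))
  expect_identical(synth_artifact(2, 1000, 7)$samples,
                   synth_artifact(2, 1000, 7)$samples)
  # the RNG state of the caller is untouched
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(synth_emg(1, 1000, 7)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("surrogate EMG is zero-mean, band-limited, burst-modulated", {
  x <- synth_emg(30, 1000, 1)
  n <- length(x$samples)
  expect_lt(abs(mean(x$samples)), 3 * sd(x$samples) / sqrt(n))
  sp <- Mod(fft(x$samples))^2
  f <- (0:(n - 1)) * 1000 / n
  inband <- (f >= 20 & f <= 450) | (f >= 1000 - 450 & f <= 1000 - 20)
  expect_gt(sum(sp[inband]) / sum(sp), 0.95)
  # bursts: the short-time RMS must swing well below and above its median
  rms <- sqrt(moving_average(emg_signal(x$samples^2, 1000), 250)$samples)
  expect_gt(stats::quantile(rms[500:n], 0.9) / stats::quantile(rms[500:n], 0.1), 3)
  expect_error(synth_emg(1, 500, 1), "1000")
})

test_that("powerline surrogate: harmonics, Nyquist guard, modulation depth", {
  fs <- 2000
  single <- pli_spec(f0 = 50, harmonics = data.frame(h = 1, amp = 1, phase = 0))
  y <- synth_pli(1, fs, single)
  expect_equal(y$samples, sin(2 * pi * 50 * (0:1999) / fs), tolerance = 1e-12)
  spec <- pli_spec(f0 = 50, seed = 3)
  expect_equal(max(spec$harmonics$h) * 50, 500)       # reaches 500 Hz
  expect_equal(spec$harmonics$amp, 1 / (1:10))
  expect_error(synth_pli(1, 900, spec), "Nyquist")
  # modulated single tone: short-time amplitude swings by (1 +/- depth)
  mspec <- pli_spec(f0 = 50, harmonics = data.frame(h = 1, amp = 1, phase = 0),
                    modulation = list(freq = 0.5, depth = 0.5))
  ym <- synth_pli(4, fs, mspec)$samples
  env <- vapply(split(ym, rep(1:100, each = 80)), function(b) max(abs(b)),
                numeric(1))  # peak per 40 ms window (2 carrier cycles)
  expect_equal(max(env), 1.5, tolerance = 0.01)
  expect_equal(min(env), 0.5, tolerance = 0.01)
})

test_that("artifact surrogate concentrates power at low frequency", {
  a <- synth_artifact(30, 1000, 5, cutoff = 4)
  n <- length(a$samples)
  sp <- Mod(fft(a$samples))^2
  f <- (0:(n - 1)) * 1000 / n
  low <- (f <= 8) | (f >= 992)
  expect_gt(sum(sp[low]) / sum(sp), 0.95)
  # a 4 Hz-bandwidth process over 30 s has ~2*4*30 effective dof, not n
  n_eff <- 2 * 4 * 30
  expect_lt(abs(mean(a$samples)), 3 * sd(a$samples) / sqrt(n_eff))
  # the comb filter removes most of its power (high-pass behaviour)
  filt <- ffc_apply(a, ffc_params(20, -1, 1000))
  expect_gt(mean(a$samples^2) / mean(filt$samples[1021:n]^2), 10)
  expect_warning(synth_artifact(1, 1000, 5, cutoff = 35), "30 Hz")
})

test_that("SNR mixing is exact by construction", {
  x <- synth_emg(5, 1000, 2)
  nz <- synth_artifact(5, 1000, 1002)
  for (snr in c(0.05, 1, 10)) {
    m <- mix_at_snr(x, nz, snr)
    added <- m$mixed$samples - x$samples
    expect_equal(mean(x$samples^2) / mean(added^2), snr, tolerance = 1e-9)
  }
  m1 <- mix_at_snr(x, nz, 1)
  expect_equal(mean((m1$scale * nz$samples)^2), mean(x$samples^2),
               tolerance = 1e-12)
  m005 <- mix_at_snr(x, nz, 0.05)
  expect_equal(mean((m005$scale * nz$samples)^2) / mean(x$samples^2), 20,
               tolerance = 1e-9)
  expect_error(mix_at_snr(x, emg_signal(numeric(5000), 1000), 1),
               "zero power")
  expect_warning(mix_at_snr(x, nz, 0.01), "0.05")
})

test_that("matched comb cancels a flat harmonic interference to numerical zero", {
  fs <- 1000
  pli <- synth_pli(5, fs, pli_spec(f0 = 50, seed = 9))
  y <- ffc_apply(pli, ffc_params(ffc_delay(fs, 50), -1, fs))$samples
  expect_lt(sqrt(mean(y[21:5000]^2)), 1e-9)
})

test_that("unipolar ADC emulation quantizes, clips, and bounds the error", {
  fs <- 1000
  cst <- adc_emulate(emg_signal(rep(2.5, 10), fs), bits = 10, full_scale = 5)
  expect_true(all(cst$codes %in% c(511L, 512L, 513L)))
  neg <- adc_emulate(emg_signal(rep(-1, 10), fs), bits = 10, full_scale = 5)
  expect_equal(neg$codes, rep(0L, 10))
  expect_equal(neg$clipped, 10L)
  ramp <- emg_signal(seq(0, 5 - 1e-9, length.out = 5000), fs)
  q <- adc_emulate(ramp, bits = 10, full_scale = 5)
  recon <- q$codes * q$lsb
  expect_lte(max(abs(recon - ramp$samples)), 5 / 2^10)
  expect_equal(q$clipped, 0L)
})
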