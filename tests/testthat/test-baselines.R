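test_that("D-spaced comb baseline nulls DC and the powerline harmonics", {
  fs <- 1000
  p <- dxn_params(20, 17)
  transient <- 20 * 16 + 1
  cst <- filter_dxn(emg_signal(rep(5, 1000), fs), p)
  expect_lt(max(abs(cst$samples[(transient + 1):1000])), 1e-12)
  y50 <- filter_dxn(tone(50, fs), p)
  expect_lt(max(abs(y50$samples[(transient + 1):5000])), 1e-9)
  x <- white_sig(1500, seed = 21)
  expect_equal(filter_dxn(x, p)$samples, dxn_loop_oracle(x$samples, 20, 17),
               tolerance = 1e-12)
})

test_that("D-spaced comb response vanishes at every multiple of fs/D", {
  fs <- 1000
  p <- dxn_params(20, 17)
  transient <- 20 * 16 + 1
  for (f in seq(0, 450, by = 50)[-1]) {   # DC covered by the constant case
    y <- filter_dxn(tone(f, fs, n = 4000), p)
    expect_lt(max(abs(y$samples[(transient + 1):4000])), 1e-9)
  }
})

test_that("FFT block filter cancels exactly the configured bins", {
  fs <- 1000
  p <- fft_filter_params(40, fft_pli_bins(fs, 40))
  expect_equal(p$zero_bins, c(0L, 1L, seq(2L, 20L, by = 2L)))
  dc <- fft_block_filter(emg_signal(rep(1, 400), fs), p)
  expect_lt(max(abs(dc$samples)), 1e-12)
  # 50 Hz = exactly 2 cycles per 40-sample block -> on bin 2, cancelled
  y50 <- fft_block_filter(tone(50, fs, n = 400), p)
  expect_lt(max(abs(y50$samples)), 1e-12)
  # 12.5 Hz is off-bin: spectral leakage leaves a residual
  y125 <- fft_block_filter(tone(12.5, fs, n = 400), p)
  expect_gt(max(abs(y125$samples)), 0.01)
  # linearity: block boundaries are fixed, so the filter distributes over +
  a <- white_sig(400, seed = 31)
  b <- white_sig(400, seed = 32)
  fa <- fft_block_filter(a, p)$samples
  fb <- fft_block_filter(b, p)$samples
  fab <- fft_block_filter(emg_signal(a$samples + b$samples, fs), p)$samples
  expect_equal(fab, fa + fb, tolerance = 1e-12)
})

test_that("one FFT block matches a direct DFT-zeroing oracle", {
  fs <- 1000
  p <- fft_filter_params(40, fft_pli_bins(fs, 40))
  x <- white_sig(40, seed = 33)
  got <- fft_block_filter(x, p)$samples
  # independent oracle: explicit DFT sums, zero bins and partners, inverse
  B <- 40
  X <- vapply(0:(B - 1), function(m)
    sum(x$samples * exp(-2i * pi * m * (0:(B - 1)) / B)), complex(1))
  kill <- c(p$zero_bins, B - p$zero_bins[p$zero_bins > 0 & p$zero_bins < B / 2])
  X[kill + 1] <- 0
  want <- Re(vapply(0:(B - 1), function(k)
    sum(X * exp(2i * pi * (0:(B - 1)) * k / B)), complex(1))) / B
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("trailing partial FFT block passes through with a warning", {
  fs <- 1000
  p <- fft_filter_params(40, fft_pli_bins(fs, 40))
  x <- emg_signal(rep(1, 50), fs)
  expect_warning(y <- fft_block_filter(x, p), "partial block")
  expect_equal(y$samples[41:50], rep(1, 10))
  expect_lt(max(abs(y$samples[1:40])), 1e-12)
})

test_that("resource profiles reproduce the published accounting", {
  ffc <- resource_profile("ffc", ffc_params(20, -1, 1000))
  expect_identical(unclass(ffc)[c("additions", "multiplications",
                                  "divisions", "memory")],
                   list(additions = 1L, multiplications = 0L, divisions = 0L,
                        memory = 20L))
  dxn <- resource_profile("dxn", dxn_params(20, 17))
  expect_identical(unclass(dxn)[c("additions", "multiplications",
                                  "divisions", "memory")],
                   list(additions = 17L, multiplications = 0L, divisions = 1L,
                        memory = 321L))
  fft <- resource_profile("fft", fft_filter_params(40, fft_pli_bins(1000, 40)))
  expect_equal(fft$memory, 40L)
  expect_gte(fft$additions, 106L)
  expect_gte(fft$multiplications, 106L)
  expect_equal(fft$divisions, 0L)
  ma_s <- resource_profile("ma-envelope", envelope_config(88))
  expect_equal(ma_s$divisions, 1L)
  ma_b <- resource_profile("ma-envelope", envelope_config(128, "block"))
  expect_equal(ma_b$divisions, 0L)  # bit shift replaces the division
})

test_that("instrumented runs confirm the analytic counts and the outputs", {
  x <- white_sig(800, seed = 41)
  ffc_ins <- instrument_filter("ffc", x, ffc_params(20, -1, 1000))
  expect_equal(ffc_ins$ops,
               list(additions = 1, multiplications = 0, divisions = 0,
                    memory = 20))
  expect_equal(ffc_ins$signal$samples,
               ffc_apply(x, ffc_params(20, -1, 1000))$samples,
               tolerance = 1e-12)
  dxn_ins <- instrument_filter("dxn", x, dxn_params(20, 17))
  expect_equal(dxn_ins$ops,
               list(additions = 17, multiplications = 0, divisions = 1,
                    memory = 321))
  expect_equal(dxn_ins$signal$samples,
               filter_dxn(x, dxn_params(20, 17))$samples, tolerance = 1e-10)
})
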