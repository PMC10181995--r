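test_that("comb delay is the exact fs/f_pli ratio and rejects misfits", {
  expect_identical(ffc_delay(1000, 50), 20L)
  expect_identical(ffc_delay(1200, 60), 20L)
  expect_identical(ffc_delay(500, 50), 10L)
  err <- expect_error(ffc_delay(1000, 60), "not an integer")
  expect_match(conditionMessage(err), "960")
  expect_match(conditionMessage(err), "1020")
})

test_that("ffc_apply matches the difference equation and its edge cases", {
  fs <- 1000
  # constant input: passthrough before the delay fills, exact zero after
  cst <- emg_signal(rep(3.7, 100), fs)
  y <- ffc_apply(cst, ffc_params(20, -1, fs))
  expect_equal(y$samples[1:20], rep(3.7, 20))
  expect_equal(y$samples[21:100], rep(0, 80))
  # impulse response: +1 at k=0, -1 at k=N
  imp <- emg_signal(c(1, numeric(99)), fs)
  h <- ffc_apply(imp, ffc_params(20, -1, fs))$samples
  expect_equal(h, c(1, numeric(19), -1, numeric(79)))
  # 50 Hz sits on a null: steady state vanishes
  y50 <- ffc_apply(tone(50, fs), ffc_params(20, -1, fs))
  expect_lt(max(abs(y50$samples[21:5000])), 1e-9)
})

test_that("ffc_apply equals the brute-force two-tap convolution oracle", {
  for (case in list(list(N = 20, alpha = -1), list(N = 7, alpha = 1),
                    list(N = 3, alpha = 0.25))) {
    x <- white_sig(2000, seed = 100 + case$N)
    got <- ffc_apply(x, ffc_params(case$N, case$alpha, 1000))$samples
    want <- comb_loop_oracle(x$samples, case$N, case$alpha)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("closed-form amplitude response: values, errors, periodicity, peak", {
  expect_equal(ffc_response(0.050, 20, -1), 0)
  expect_equal(ffc_response(0.025, 20, -1), 2)
  expect_equal(ffc_response(0.0125, 20, -1), sqrt(2))
  expect_equal(ffc_response(0, 20, 1), 2)       # alpha=+1 passes DC
  expect_error(ffc_response(0.1, 20, 0.5), "alpha")
  expect_error(ffc_response(0.6, 20, -1), "0, 0.5")
  grid <- seq(0, 0.5, length.out = 20001)
  g <- ffc_response(grid, 20, -1)
  expect_lte(max(g), 2)
  expect_equal(max(g), 2)  # attained on the grid midway between nulls
  # response is periodic with period 1/N
  sub <- grid[grid + 1 / 20 <= 0.5]
  expect_equal(ffc_response(sub, 20, -1), ffc_response(sub + 1 / 20, 20, -1))
})

test_that("null and cutoff frequencies follow the closed forms", {
  p <- ffc_params(20, -1, 1000)
  expect_equal(ffc_nulls(p, 500), seq(0, 500, by = 50))
  expect_equal(ffc_nulls(ffc_params(20, 1, 1000), 200), c(25, 75, 125, 175))
  expect_equal(ffc_nulls(ffc_params(1, -1, 100), 50), 0)
  expect_equal(ffc_cutoffs(p, 100), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(ffc_cutoffs(ffc_params(20, -1, 1200), 20), 15)
  # every cutoff is fs/(4N) from its nearest null
  cuts <- ffc_cutoffs(p, 500)
  nulls <- ffc_nulls(p, 500)
  gap <- vapply(cuts, function(f) min(abs(f - nulls)), numeric(1))
  expect_equal(gap, rep(1000 / (4 * 20), length(cuts)))
  expect_error(ffc_cutoffs(ffc_params(20, 1, 1000), 100), "alpha = -1")
})

test_that("zero DC gain: constant offsets vanish from the steady state", {
  x <- white_sig(3000, seed = 11)
  p <- ffc_params(20, -1, 1000)
  y0 <- ffc_apply(x, p)$samples
  y1 <- ffc_apply(emg_signal(x$samples + 123.4, x$fs), p)$samples
  expect_equal(y1[21:3000], y0[21:3000])
  expect_false(isTRUE(all.equal(y1[1:20], y0[1:20])))  # transient differs
})

test_that("measured steady-state sinusoid gain matches the closed form", {
  fs <- 1000
  M <- 4096                                # projection window, exact bins
  set.seed(5)
  bins <- sample(30:1800, 20)
  for (b in bins) {
    f <- b * fs / M
    n <- 20 + M
    x <- tone(f, fs, n = n)
    y <- ffc_apply(x, ffc_params(20, -1, fs))$samples[21:n]
    amp <- projected_amplitude(y, f, fs)
    expect_lt(abs(amp - ffc_response(f / fs, 20, -1)), 1e-6)
  }
})
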