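test_that("noiseless demodulation reaches ppm amplitude and 0.01 degree phase accuracy", {
  fs <- 37500
  f <- 1000
  t <- (0:(100 * fs / f - 1)) / fs
  d0 <- demodulate(cos(2 * pi * f * t), fs = fs, ref = reference_config(f))
  expect_lt(abs(d0$amplitude - 1) * 1e6, 1)          # < 1 ppm
  expect_lt(abs(d0$phase) * 180 / pi, 0.01)          # < 0.01 degrees
  d30 <- demodulate(cos(2 * pi * f * t - pi / 6), fs = fs,
                    ref = reference_config(f))
  expect_lt(abs(d30$phase - pi / 6) * 180 / pi, 0.01)
  d45 <- demodulate(0.3 * cos(2 * pi * f * t - pi / 4), fs = fs,
                    ref = reference_config(f))
  expect_equal(d45$phase, pi / 4, tolerance = 1e-6)
  expect_equal(d45$amplitude, 0.3, tolerance = 1e-9)
})

test_that("odd harmonics at equal amplitude leave the fundamental estimate unchanged", {
  fs <- 37500
  f <- 750  # 50 samples per period
  t <- (0:(50 * fs / f - 1)) / fs
  x <- cos(2 * pi * f * t) + cos(2 * pi * 3 * f * t + 0.4)
  d <- demodulate(x, fs = fs, ref = reference_config(f))
  expect_equal(d$amplitude, 1, tolerance = 1e-9)
})

test_that("amplitude is invariant to reference phase; phase is recovered at any phi_r", {
  fs <- 20000
  f <- 100
  t <- (0:(20 * fs / f - 1)) / fs
  x <- 0.7 * cos(2 * pi * f * t - 1.1)
  for (phi_r in seq(-3, 3, by = 0.75)) {
    d <- demodulate(x, fs = fs, ref = reference_config(f, phi_r = phi_r))
    expect_equal(d$amplitude, 0.7, tolerance = 1e-9)
    expect_equal(d$phase, 1.1, tolerance = 1e-6)
  }
})

test_that("the phasor convention reproduces the signal", {
  fs <- 10000
  f <- 50
  t <- (0:(10 * fs / f - 1)) / fs
  x <- 0.4 * cos(2 * pi * f * t - 0.9)
  d <- demodulate(x, fs = fs, ref = reference_config(f))
  expect_equal(Re(d$phasor * exp(1i * 2 * pi * f * t)), x, tolerance = 1e-6)
})

test_that("whole-period truncation discards trailing fractional periods", {
  fs <- 1000
  f <- 10
  n <- 1234  # 12.34 periods
  t <- (0:(n - 1)) / fs
  d <- demodulate(cos(2 * pi * f * t), fs = fs, ref = reference_config(f))
  expect_identical(d$n_periods, 12)
  expect_equal(d$amplitude, 1, tolerance = 1e-9)
  expect_error(demodulate(cos(2 * pi * f * t[1:50]), fs = fs,
                          ref = reference_config(f)), "period")
})

test_that("reference frequency mismatch is rejected", {
  wf <- synthesize_waveforms(nominal_phantom(), 10, n_periods = 2)
  expect_error(demodulate(wf, "u1", ref = reference_config(11)), "match")
})

test_that("integration with the low-pass engaged equals pure integration", {
  fs <- 37500
  f <- 1000
  t <- (0:(100 * fs / f - 1)) / fs
  x <- 0.8 * cos(2 * pi * f * t - 0.5)
  plain <- demodulate(x, fs = fs, ref = reference_config(f))
  filt <- demodulate(x, fs = fs, ref = reference_config(f),
                     filt = filter_config(1, 50))
  filt2 <- demodulate(x, fs = fs, ref = reference_config(f),
                      filt = filter_config(2, 50))
  expect_equal(filt$amplitude, plain$amplitude, tolerance = 1e-3)
  expect_equal(filt2$amplitude, plain$amplitude, tolerance = 1e-3)
  expect_equal(filt$phase, plain$phase, tolerance = 1e-3)
})

test_that("the discrete RC section has unity DC gain and a -3 dB corner", {
  fs <- 37500
  y <- apply_lowpass(rep(2.5, 1000), fs, 1, cutoff = 100)
  expect_equal(y, rep(2.5, 1000), tolerance = 1e-12)
  # sinusoid at the corner: steady-state amplitude ratio 1/sqrt(2) within 2%
  f <- 100
  t <- (0:(fs - 1)) / fs  # 1 s = 100 periods, RC = 16 ms
  x <- sin(2 * pi * f * t)
  y <- apply_lowpass(x, fs, 1, cutoff = f, init = "zero")
  tail_rms <- sqrt(mean(y[(fs / 2):fs]^2))
  expect_equal(tail_rms * sqrt(2), 1 / sqrt(2), tolerance = 0.02)
  expect_error(apply_lowpass(x, fs, 1, cutoff = fs), "cutoff")
  expect_error(apply_lowpass(x, fs, 3, cutoff = 10), "order")
})

test_that("FFT spectrum is normalized to peak amplitude with a correct noise floor", {
  fs <- 1000
  n <- 1000
  t <- (0:(n - 1)) / fs
  sp <- fft_spectrum(cos(2 * pi * 50 * t), fs = fs)
  expect_equal(sp$level_db[sp$freq_hz == 50], 0, tolerance = 1e-9)
  sp_h <- fft_spectrum(cos(2 * pi * 50 * t), fs = fs, window = "hann")
  expect_equal(sp_h$amplitude_v[sp_h$freq_hz == 50], 1, tolerance = 1e-6)
  # noiseless phantom synthesis at 0.8 Hz peaks at 0.8 Hz
  wf <- synthesize_waveforms(nominal_phantom(), 0.8, n_periods = 8)
  spu <- fft_spectrum(wf, "u2")
  expect_equal(spu$freq_hz[which.max(spu$amplitude_v)], 0.8)
  # Parseval: mean squared bin amplitude of white noise is 4 sigma^2 / n
  withr::with_seed(11, x <- rnorm(n, sd = 0.1))
  spn <- fft_spectrum(x, fs = fs)
  ratio <- mean(spn$amplitude_v[-1]^2) / (4 * 0.1^2 / n)
  expect_lt(abs(10 * log10(ratio)), 3)
})

test_that("demodulated amplitude of pure noise decays as 1/sqrt(integration length)", {
  fs <- 1000
  f <- 10
  amp_for <- function(n, seed) {
    withr::with_seed(seed, x <- rnorm(n, sd = 0.1))
    demodulate(x, fs = fs, ref = reference_config(f))$amplitude
  }
  a_short <- vapply(1:60, function(s) amp_for(2000, s), numeric(1))
  a_long <- vapply(1:60, function(s) amp_for(8000, 1000 + s), numeric(1))
  rms <- function(v) sqrt(mean(v^2))
  # absolute level: RMS amplitude of noise-only estimate is 2 sigma / sqrt(m)
  expect_equal(rms(a_short), 2 * 0.1 / sqrt(2000), tolerance = 0.3)
  expect_equal(rms(a_short) / rms(a_long), 2, tolerance = 0.3)
})
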