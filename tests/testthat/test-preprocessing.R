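test_that("remove_dc subtracts the arithmetic mean", {
  expect_equal(remove_dc(emg_record(c(5, 5, 5, 5), 10))$samples,
               c(0, 0, 0, 0))
  expect_equal(remove_dc(emg_record(c(1, 2, 3, 4), 10))$samples,
               c(-1.5, -0.5, 0.5, 1.5))
  x <- sin(2 * pi * (1:100) / 10)
  x <- x - mean(x)
  expect_equal(remove_dc(emg_record(x, 10))$samples, x, tolerance = 1e-12)
})

test_that("band filters pass in-band tones and reject out-of-band tones", {
  bp <- filter_spec("band-pass", 2, 25, 350)
  bs <- filter_spec("band-stop", 2, 47, 53)
  ratio <- function(f, spec) {
    x <- make_tone(f)
    rms(edge_trim(apply_filter(x, spec, fs = fs_default))) /
      rms(edge_trim(x))
  }
  expect_gte(ratio(100, bp), 0.9)   # deep in the pass-band
  expect_lte(ratio(50, bs), 0.1)    # centre of the stop-band
  # >= 1 octave outside: attenuation at least 90%
  expect_lte(ratio(10, bp), 0.1)
  expect_lte(ratio(700, bp), 0.1)
})

test_that("low-side attenuation matches the designed transfer function", {
  # measured RMS ratio for a 10 Hz tone against the analytic gain of the
  # designed filter, evaluated independently on the unit circle
  bp <- filter_spec("band-pass", 2, 25, 350)
  x <- make_tone(10, dur = 6)
  measured <- rms(edge_trim(apply_filter(x, bp, fs = fs_default),
                            trim_s = 1)) / rms(edge_trim(x, trim_s = 1))
  predicted <- butter_gain_oracle(2, 25, 350, 10, fs_default)
  expect_lte(measured, 0.3)
  expect_equal(measured, predicted, tolerance = 0.05)
  expect_equal(filter_gain(bp, 10, fs_default), predicted,
               tolerance = 1e-9)
})

test_that("designed magnitude response is -3 dB at the corners", {
  for (spec in list(filter_spec("band-pass", 2, 25, 350,
                                zero_phase = FALSE),
                    filter_spec("band-pass", 4, 80, 350,
                                zero_phase = FALSE),
                    filter_spec("band-stop", 2, 47, 53,
                                zero_phase = FALSE))) {
    g_db <- 20 * log10(filter_gain(spec, c(spec$low_hz, spec$high_hz),
                                   fs_default))
    expect_true(all(abs(g_db - (-3)) < 0.5))
  }
})

test_that("filters refuse invalid corners and too-short inputs", {
  expect_error(apply_filter(make_tone(10), filter_spec("band-pass", 2,
                                                       25, 1100),
                            fs = fs_default), "Nyquist|invalid")
  expect_error(apply_filter(rnorm(10), filter_spec("band-pass", 2, 25,
                                                   350),
                            fs = fs_default), "too short")
  expect_error(filter_spec("band-pass", 2, 100, 50), "low_hz")
})

test_that("conditioning concentrates broadband power with a 50 Hz notch", {
  set.seed(42)
  rec <- emg_record(rnorm(8 * fs_default), fs_default)
  out <- preprocess(rec)
  expect_equal(length(out$samples), length(rec$samples))
  expect_lt(abs(mean(out$samples)), 1e-4 * stats::sd(out$samples))
  ps <- power_spectrum(out)
  band_power <- function(f0, width = 2) {
    mean(ps$power[ps$freqs >= f0 - width & ps$freqs <= f0 + width])
  }
  expect_lt(band_power(50), 0.2 * band_power(100))  # notch
  expect_lt(band_power(10), 0.2 * band_power(100))  # below band
  expect_lt(band_power(450), 0.2 * band_power(100)) # above band
})

test_that("conditioning annihilates pure 50 Hz interference and pure DC", {
  tone50 <- emg_record(make_tone(50, dur = 6), fs_default)
  out <- preprocess(tone50)
  expect_lte(rms(edge_trim(out$samples)) / rms(tone50$samples), 0.05)
  dc <- emg_record(rep(2.5, 6 * fs_default), fs_default)
  expect_lt(rms(preprocess(dc)$samples), 1e-9)
})

test_that("conditioning is linear in the input amplitude", {
  set.seed(7)
  x <- rnorm(4 * fs_default)
  y1 <- preprocess(emg_record(x, fs_default))$samples
  for (a in c(0.25, 3, -2)) {
    ya <- preprocess(emg_record(a * x, fs_default))$samples
    expect_equal(ya, a * y1, tolerance = 1e-9)
  }
})

test_that("zero-phase filtering introduces no group delay", {
  # band-limited burst: 100 Hz tone gated in the middle of the record
  n <- 6 * fs_default
  x <- numeric(n)
  k <- (2 * fs_default):(4 * fs_default)
  x[k] <- sin(2 * pi * 100 * k / fs_default) *
    exp(-((k - 3 * fs_default) / (0.3 * fs_default))^2)
  y <- apply_filter(x, filter_spec("band-pass", 2, 25, 350),
                    fs = fs_default)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # a causal single pass through the narrow low band, by contrast,
  # delays a 50 Hz burst measurably
  xb <- numeric(n)
  xb[k] <- sin(2 * pi * 50 * k / fs_default) *
    exp(-((k - 3 * fs_default) / (0.3 * fs_default))^2)
  yz <- apply_filter(xb, filter_spec("band-pass", 4, 25, 79),
                     fs = fs_default)
  yc <- apply_filter(xb, filter_spec("band-pass", 4, 25, 79,
                                     zero_phase = FALSE),
                     fs = fs_default)
  ccz <- stats::ccf(xb, yz, lag.max = 40, plot = FALSE)
  ccc <- stats::ccf(xb, yc, lag.max = 40, plot = FALSE)
  expect_equal(ccz$lag[which.max(ccz$acf)], 0)
  expect_true(ccc$lag[which.max(ccc$acf)] != 0)
})

test_that("preprocess requires headroom above the band-pass corner", {
  expect_error(preprocess(emg_record(rnorm(1000), fs = 600)),
               "sampling rate")
})
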