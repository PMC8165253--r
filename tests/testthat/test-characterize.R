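test_that("frequency response handles delta, Gaussian and degenerate inputs", {
  fs <- 125e6
  # discrete delta: flat spectrum, bandwidth = Nyquist
  delta <- c(rep(0, 32), 1, rep(0, 31))
  frD <- frequencyResponse(delta, fs)
  expect_true(all(abs(frD@magnitudeDB) < 1e-9))
  expect_equal(bandwidth3dB(frD), fs / 2)

  # Gaussian pulse: closed-form -3 dB point sqrt(ln 2) / (2 pi sigma)
  sigma <- 12e-9
  t <- (0:1023 - 512) / fs
  fr <- frequencyResponse(exp(-t^2 / (2 * sigma^2)), fs)
  binWidth <- fr@freqs[2] - fr@freqs[1]
  expect_lt(abs(bandwidth3dB(fr) - sqrt(log(2)) / (2 * pi * sigma)), binWidth)

  expect_error(frequencyResponse(rep(0, 64), fs), "all zero")
})

test_that("frequency response is scale-invariant", {
  fs <- 100e6
  w <- exp(-((0:255 - 90) / 20)^2) * sin(2 * pi * 0.1 * (0:255))
  a <- frequencyResponse(w, fs)
  b <- frequencyResponse(1e4 * w, fs)
  expect_equal(a@magnitudeDB, b@magnitudeDB, tolerance = 1e-6)
  expect_equal(bandwidth3dB(a), bandwidth3dB(b))
})

test_that("the packaged default sensor kernel round-trips its 23 MHz design", {
  s <- makeSensorModel()
  fr <- frequencyResponse(s@impulseResponse, sampleRate(s))
  binWidth <- fr@freqs[2] - fr@freqs[1]
  expect_lt(abs(bandwidth3dB(fr) - 23e6), binWidth)
})

test_that("directivity maps count, normalise and measure coverage correctly", {
  fs <- 125e6
  pulse <- exp(-((0:127 - 40) / 8)^2)
  angles <- seq(-90, 90, by = 1)
  # bench bookkeeping: a 1-degree sweep holds 181 records
  iso <- directivityMap(lapply(angles, function(a) pulse), angles, fs)
  expect_equal(length(iso@angles), 181L)
  expect_equal(nrow(iso@gain), 181L)
  expect_equal(max(iso@gain), 1)
  expect_equal(iso@coverage, 180)

  # cosine-gain sensor: half gain at +/-60 deg -> 120 deg coverage
  cosSweep <- lapply(angles, function(a) cosineDirectivity(1)(a) * pulse)
  cm <- directivityMap(cosSweep, angles, fs)
  expect_lte(abs(cm@coverage - 120), 2)
  # symmetric sweep gives a symmetric map
  expect_equal(cm@gain, cm@gain[rev(seq_len(181)), , drop = FALSE],
               tolerance = 1e-12)

  expect_error(directivityMap(list(pulse, pulse), c(0, 0), fs), "duplicate")
  expect_error(directivityMap(list(pulse, pulse), c(10, 5), fs), "increasing")
})

test_that("NEP estimation is a calibrated standard deviation", {
  expect_equal(estimateNEP(rep(0, 1000)), 0)
  set.seed(2024)
  rec <- rnorm(1e6, sd = 65.8)
  expect_lt(abs(estimateNEP(rec) - 65.8) / 65.8, 0.01)
  expect_equal(estimateNEP(rec, calibrationGain = 2), 2 * estimateNEP(rec))
  expect_error(estimateNEP(rnorm(50)), "insufficient")
  # near-unbiased already at 1e4 samples (averaged over fixed seeds)
  ests <- vapply(1:20, function(s) { set.seed(s); estimateNEP(rnorm(1e4, sd = 10)) },
                 numeric(1))
  expect_lt(abs(mean(ests) - 10) / 10, 0.01)
})
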