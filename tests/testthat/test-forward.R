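test_that("sphere N-wave matches its closed-form properties", {
  center <- c(0, 0, 3e-3); a <- 50e-6; d <- 3e-3; sos <- 1500
  ts <- seq((d - 2 * a) / sos, (d + 2 * a) / sos, by = 1e-11)
  p <- spherePressureWaveform(center, a, 2, c(0, 0, 0), ts, sos)
  expect_equal(max(abs(p)), 2 * a / (2 * d), tolerance = 1e-2)
  # equal positive and negative lobes: integral over the support is zero
  expect_lt(abs(sum(p)) / sum(abs(p)), 1e-3)
  # zero amplitude is identically zero
  expect_true(all(spherePressureWaveform(center, a, 0, c(0, 0, 0), ts, sos) == 0))
  expect_error(spherePressureWaveform(center, a, 1, center + c(0, 0, 1e-5),
                                      ts, sos), "inside")
})

test_that("N-wave agrees with the spherical-means wave-equation oracle", {
  center <- c(0.4e-3, -0.2e-3, 2.5e-3); a <- 150e-6; sos <- 1500
  det <- c(0, 0, 0)
  d <- sqrt(sum((center - det)^2))
  # grid chosen so no sample coincides with the waveform's support edges
  ts <- seq((d - 1.45 * a) / sos, (d + 1.55 * a) / sos, length.out = 239)
  p <- spherePressureWaveform(center, a, 3, det, ts, sos)
  pOracle <- sphericalMeansOracle(center, a, 3, det, ts, sos)
  expect_lt(sqrt(sum((p - pOracle)^2) / sum(p^2)), 1e-3)
})

test_that("simulated signal sets honour geometry, arrival time and determinism", {
  # symmetric (tail-free) kernel so convolution preserves the N-wave midpoint
  sensor <- makeSensorModel(tailAmplitude = 0)
  g <- makeRasterGeometry(5, 5, 4e-4, 10, origin = c(-8e-4, -8e-4, 0))
  # empty phantom, noise off -> all-zero signals
  empty <- makeAbsorberPhantom(matrix(numeric(0), 0, 3), numeric(0),
                               matrix(numeric(0), 0, 1,
                                      dimnames = list(NULL, "800")),
                               character(0), numeric(0), 1500, "null")
  z <- simulateSignals(empty, g, sensor, 125e6, 300, 800)
  expect_true(all(signalData(z) == 0))

  depth <- 3e-3
  ph <- makeAbsorberPhantom(rbind(c(0, 0, depth)), 100e-6, c("800" = 1))
  ss <- simulateSignals(ph, g, sensor, 125e6, 500, 800)
  d <- signalData(ss)
  # earliest arrival at the scan point directly above the absorber
  onsets <- apply(abs(d) > 0.25 * max(abs(d)), c(1, 2),
                  function(v) which(v)[1])
  expect_equal(unname(which(onsets == min(onsets), arr.ind = TRUE)[1, ]),
               c(3, 3))
  # N-wave support midpoint at distance / sos within one sample
  tr <- d[3, 3, ]
  mid <- ((which.max(tr) + which.min(tr)) / 2 - 1) / 125e6
  expect_lt(abs(mid - depth / 1500), 1 / 125e6)
  # bit-identical reruns
  expect_identical(signalData(simulateSignals(ph, g, sensor, 125e6, 500, 800,
                                              noiseSeed = 5)),
                   signalData(simulateSignals(ph, g, sensor, 125e6, 500, 800,
                                              noiseSeed = 5)))
  expect_error(simulateSignals(ph, g, sensor, 40e6, 500, 800), "2.5x")
  expect_error(simulateSignals(ph, g, sensor, 125e6, 500, 532), "532")
})

test_that("the forward model is linear in the phantom (superposition)", {
  sensor <- makeSensorModel()
  g <- makeRasterGeometry(4, 4, 3e-4, 10, origin = c(-4.5e-4, -4.5e-4, 0))
  phA <- makeAbsorberPhantom(rbind(c(-2e-4, 0, 2e-3)), 80e-6, c("800" = 1))
  phB <- makeAbsorberPhantom(rbind(c(3e-4, 1e-4, 3.2e-3)), 120e-6, c("800" = 2))
  phAB <- makeAbsorberPhantom(rbind(c(-2e-4, 0, 2e-3), c(3e-4, 1e-4, 3.2e-3)),
                              c(80e-6, 120e-6),
                              matrix(c(1, 2), 2, 1, dimnames = list(NULL, "800")))
  sA <- signalData(simulateSignals(phA, g, sensor, 125e6, 420, 800))
  sB <- signalData(simulateSignals(phB, g, sensor, 125e6, 420, 800))
  sAB <- signalData(simulateSignals(phAB, g, sensor, 125e6, 420, 800))
  expect_equal(sAB, sA + sB, tolerance = 1e-12)
})

test_that("directivity attenuates oblique incidence in the forward model", {
  sensor <- makeSensorModel(directivity = cosineDirectivity(1))
  g <- makeRasterGeometry(3, 1, 2e-3, 10, origin = c(0, 0, 0))
  # source above detector 1; detectors 2 and 3 see it at 45 and 63 deg
  ph <- makeAbsorberPhantom(rbind(c(0, 0, 2e-3)), 100e-6, c("800" = 1))
  ss <- simulateSignals(ph, g, sensor, 125e6, 700, 800)
  peaks <- apply(abs(signalData(ss)[, 1, ]), 1, max)
  expect_true(peaks[1] > peaks[2] && peaks[2] > peaks[3])
})

test_that("injected noise matches the sensor NEP", {
  sensor <- makeSensorModel(nep = 65.8)
  g <- makeRasterGeometry(32, 32, 1e-4, 10)
  empty <- makeAbsorberPhantom(matrix(numeric(0), 0, 3), numeric(0),
                               matrix(numeric(0), 0, 1,
                                      dimnames = list(NULL, "800")),
                               character(0), numeric(0), 1500, "null")
  ss <- simulateSignals(empty, g, sensor, 125e6, 1024, 800, noiseSeed = 99)
  expect_equal(length(signalData(ss)), 32L * 32L * 1024L)  # > 1e6 samples
  expect_lt(abs(sd(signalData(ss)) - 65.8) / 65.8, 0.02)
})
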