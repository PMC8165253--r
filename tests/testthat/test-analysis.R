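test_that("Gaussian LSF fits recover known widths and match the half-max oracle", {
  grid <- makeReconGrid(c(81L, 5L, 121L), 10e-6, c(-4e-4, -2e-5, 1.6e-3))
  # sigma_z = 38.2 um -> FWHM = 2 sqrt(2 ln 2) * 38.2 = 90 um
  vol <- gaussianBlobVolume(grid, c(0, 0, 2.2e-3), c(38.2e-6, 1e9, 38.2e-6))
  rep <- estimateResolution(vol, cbind(0, 0, 2.2e-3),
                            searchRadius = 3e-4, profileHalfWidth = 3e-4)
  expect_lt(abs(rep@wires$axialFWHM - 90e-6), 10e-6)      # one voxel
  # symmetric blob: axial equals lateral
  expect_equal(rep@wires$axialFWHM, rep@wires$lateralFWHM, tolerance = 1e-3)
  # brute-force half-maximum crossing agrees
  zs <- gridCoords(grid, 3)
  prof <- volumeValues(vol)[41, 3, ]
  expect_lt(abs(rep@wires$axialFWHM - fwhmHalfMax(zs, prof)), 10e-6)
})

test_that("FWHM estimator tracks the half-max oracle across random widths", {
  set.seed(7)
  grid <- makeReconGrid(c(61L, 3L, 161L), 10e-6, c(-3e-4, -1e-5, 1e-3))
  for (i in 1:20) {
    sz <- runif(1, 25e-6, 90e-6)
    vol <- gaussianBlobVolume(grid, c(0, 0, 1.8e-3), c(40e-6, 1e9, sz))
    rep <- estimateResolution(vol, cbind(0, 0, 1.8e-3),
                              searchRadius = 2e-4, profileHalfWidth = 4e-4)
    oracle <- fwhmHalfMax(gridCoords(grid, 3), volumeValues(vol)[31, 2, ])
    expect_lt(abs(rep@wires$axialFWHM - oracle), 10e-6)
  }
})

test_that("pulse-duration resolution limit is duration times speed", {
  expect_equal(pulseLimitedResolution(25e-9, 1500), 37.5e-6)
  expect_equal(pulseLimitedResolution(50e-9, 1500), 75e-6)
  expect_equal(pulseLimitedResolution(1e-12, 1500), 1.5e-9)
  expect_error(pulseLimitedResolution(0, 1500), "> 0")
})

test_that("depth-coded MIP takes per-ray maxima with a shallow tie-break", {
  grid <- makeReconGrid(c(6L, 5L, 60L), 50e-6)
  v <- array(0, grid@shape)
  v[2, 3, 17] <- 1
  vol <- new("ReconVolume", grid = grid, values = v, wavelength = NA_real_,
             envelopeApplied = TRUE)
  m <- depthCodedMIP(vol)
  expect_equal(sum(m$intensity > 0), 1L)
  expect_equal(m$depthIndex[2, 3], 17L)
  expect_equal(m$depth[2, 3], gridCoords(grid, 3)[17])

  # two voxels on one ray: the brighter wins, depth is its arg-max
  v[2, 3, 50] <- 0.6
  vol@values <- v
  m2 <- depthCodedMIP(vol)
  expect_equal(m2$intensity[2, 3], 1)
  expect_equal(m2$depthIndex[2, 3], 17L)

  # all-equal volume: tie broken towards the first (shallowest) index
  vol@values <- array(1, grid@shape)
  m3 <- depthCodedMIP(vol)
  expect_true(all(m3$intensity == 1))
  expect_true(all(m3$depthIndex == 1L))

  # the intensity layer equals a brute-force per-ray maximum
  set.seed(3)
  vol@values <- array(runif(prod(grid@shape)), grid@shape)
  m4 <- depthCodedMIP(vol)
  brute <- matrix(0, 6, 5)
  for (i in 1:6) for (j in 1:5) brute[i, j] <- max(vol@values[i, j, ])
  expect_equal(m4$intensity, brute)
})

test_that("hysteresis segmentation finds tubes, filters size and is threshold-monotone", {
  grid <- makeReconGrid(c(40L, 20L, 30L), 50e-6)
  set.seed(11)
  v <- array(runif(prod(grid@shape), 0, 0.05), grid@shape)
  v[5:35, 5, 10] <- 1          # bright tube, 31 voxels
  v[5:25, 15, 20] <- 0.9       # second tube, 21 voxels
  vol <- new("ReconVolume", grid = grid, values = v, wavelength = NA_real_,
             envelopeApplied = TRUE)
  seg <- segmentVessels(vol, 0.5, 0.2, minVoxels = 5L)
  expect_equal(nrow(seg@table), 2L)
  expect_equal(seg@table$voxelCount[1], max(seg@table$voxelCount))

  # min size filter can empty the result
  seg0 <- segmentVessels(vol, 0.5, 0.2, minVoxels = 100L)
  expect_equal(nrow(seg0@table), 0L)

  # raising the seed threshold never increases the seeded component count
  nComp <- vapply(c(0.3, 0.5, 0.7, 0.95), function(hi)
    nrow(segmentVessels(vol, hi, 0.2, minVoxels = 1L)@table), numeric(1))
  expect_true(all(diff(nComp) <= 0))

  # nothing above the seed threshold -> empty with a warning
  dim3 <- grid@shape
  flat <- new("ReconVolume", grid = grid, values = array(0, dim3),
              wavelength = NA_real_, envelopeApplied = TRUE)
  expect_warning(segEmpty <- segmentVessels(flat, 0.5, 0.2), "empty")
  expect_equal(nrow(segEmpty@table), 0L)
})

test_that("per-label mean amplitudes and grid checks behave", {
  grid <- makeReconGrid(c(10L, 10L, 10L), 50e-6)
  v <- array(0, grid@shape); v[2:4, 2:4, 2:4] <- 3
  vol <- new("ReconVolume", grid = grid, values = v, wavelength = 800,
             envelopeApplied = TRUE)
  seg <- segmentVessels(vol, 0.5, 0.2, minVoxels = 1L)
  paa <- meanPAA(seg, list("800" = vol), normalize = FALSE)
  expect_equal(paa$paa800, 3)
  other <- new("ReconVolume", grid = makeReconGrid(c(9L, 9L, 9L), 50e-6),
               values = array(1, c(9, 9, 9)), wavelength = 800,
               envelopeApplied = TRUE)
  expect_error(meanPAA(seg, list("800" = other)), "grid")
})

test_that("diffusion fluence follows the closed form and its symmetries", {
  grid <- makeReconGrid(c(8L, 6L, 50L), 50e-6)
  # mu_a = 0.1 /mm, mu_s' = 1.0 /mm -> mu_eff = 0.5745 /mm
  f <- computeFluence(0, grid, muA = 100, muSPrime = 1000)
  muEff <- sqrt(3 * 100 * 1100)
  expect_equal(muEff, 574.4563, tolerance = 1e-6)
  iz2mm <- which.min(abs(gridCoords(grid, 3) - 2e-3))
  expect_equal(volumeValues(f)[1, 1, iz2mm],
               exp(-muEff * gridCoords(grid, 3)[iz2mm]), tolerance = 1e-12)
  expect_equal(exp(-muEff * 2e-3), 0.3170, tolerance = 1e-4)
  # flat surface: constant on every z slice; monotone non-increasing in depth
  vals <- volumeValues(f)
  expect_true(all(apply(vals, 3, function(s) diff(range(s)) == 0)))
  expect_true(all(apply(vals, c(1, 2), diff) <= 0))
  # vanishing absorption: fluence approaches 1 everywhere
  f0 <- computeFluence(0, grid, muA = 1e-6, muSPrime = 1e-6)
  expect_true(all(volumeValues(f0) > 0.9999))
})

test_that("fluence compensation inverts the illumination decay", {
  grid <- makeReconGrid(c(4L, 4L, 60L), 50e-6)
  f <- computeFluence(0, grid, muA = 150, muSPrime = 1200)
  # a depth-constant absorber seen through the fluence decay
  truth <- array(2, grid@shape)
  observed <- new("ReconVolume", grid = grid,
                  values = truth * volumeValues(f), wavelength = NA_real_,
                  envelopeApplied = TRUE)
  comp <- fluenceCompensate(observed, f, floor = 0.01)
  above <- volumeValues(f) >= 0.01
  expect_lt(max(abs(volumeValues(comp)[above] - 2) / 2), 0.01)
  # the clamp caps the gain at 1/floor
  expect_true(all(volumeValues(comp) <= 2 + 1e-9))

  # unit fluence leaves the volume unchanged
  surfaceBelow <- max(gridCoords(grid, 3))
  f1 <- computeFluence(surfaceBelow, grid, muA = 100, muSPrime = 1000)
  expect_true(all(volumeValues(f1) == 1))
  expect_identical(volumeValues(fluenceCompensate(observed, f1, 0.5)),
                   volumeValues(observed))
})

test_that("dual-wavelength differencing normalises by total energy", {
  grid <- makeReconGrid(c(8L, 8L, 12L), 50e-6)
  set.seed(5)
  a <- array(runif(prod(grid@shape)), grid@shape)
  b <- array(runif(prod(grid@shape)), grid@shape)
  volA <- new("ReconVolume", grid = grid, values = a, wavelength = 1064,
              envelopeApplied = TRUE)
  volB <- new("ReconVolume", grid = grid, values = b, wavelength = 800,
              envelopeApplied = TRUE)
  dw <- dualWavelengthDifference(volA, volB)
  expect_equal(sum(dw$norm1064), 1)
  expect_equal(sum(dw$norm800), 1)
  # identical inputs give an identically zero difference
  dw0 <- dualWavelengthDifference(volA, volA)
  expect_true(all(dw0$difference == 0))
  # invariance to rescaling either input by a positive constant
  volA7 <- volA; volA7@values <- 7 * volA7@values
  expect_equal(dualWavelengthDifference(volA7, volB)$difference,
               dw$difference, tolerance = 1e-12)
  zero <- volA; zero@values[] <- 0
  expect_error(dualWavelengthDifference(zero, volB), "total energy")
})
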