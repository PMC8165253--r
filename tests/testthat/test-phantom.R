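test_that("wire phantoms are dense sphere chains at the stated depths", {
  depths <- seq(1e-3, 5e-3, length.out = 9)
  p <- makeWirePhantom(9, 9e-6, depths, 1500)
  expect_equal(length(unique(p@labels)), 9L)
  expect_true(all(p@radii == 4.5e-6))
  for (w in seq_len(9)) {
    ctr <- p@centers[p@labels == sprintf("wire%d", w), , drop = FALSE]
    expect_true(all(ctr[, 3] == depths[w]))
    gaps <- sqrt(rowSums(diff(ctr)^2))
    expect_lte(max(gaps), 4.5e-6)           # spacing bounded by the radius
  }
  single <- makeWirePhantom(1, 9e-6, 1e-3, 1500)
  expect_true(all(single@centers[, 3] == 1e-3))
  expect_error(makeWirePhantom(1, 9e-6, numeric(0), 1500), "non-empty")
  expect_error(makeWirePhantom(2, 9e-6, c(1e-3, -1e-3), 1500), "positive")
})

test_that("vessel amplitudes follow the extinction-weighted hemoglobin model", {
  # two phantoms identical except for so2 (same seed => same geometry)
  pHi <- makeVesselPhantom(7, nBranches = 3, so2Artery = 0.95, so2Vein = 0.95)
  pLo <- makeVesselPhantom(7, nBranches = 3, so2Artery = 0.65, so2Vein = 0.65)
  expect_identical(pHi@centers, pLo@centers)
  # isosbestic: 800 nm amplitude independent of so2 at fixed total hemoglobin
  expect_equal(pHi@amplitudes[, "800"], pLo@amplitudes[, "800"])
  # 1,064 nm: the more oxygenated phantom is strictly brighter
  expect_true(all(pHi@amplitudes[, "1064"] > pLo@amplitudes[, "1064"]))
})

test_that("degenerate extinction collapses the so2 dependence", {
  tbl <- data.frame(wavelength = c(800, 1064), eHbO2 = c(800, 500),
                    eHb = c(800, 500))
  a <- makeVesselPhantom(3, nBranches = 2, so2Artery = 0, so2Vein = 0,
                         extinctionTable = tbl)
  b <- makeVesselPhantom(3, nBranches = 2, so2Artery = 1, so2Vein = 1,
                         extinctionTable = tbl)
  expect_equal(a@amplitudes, b@amplitudes)
})

test_that("vessel phantom generation is seed-deterministic", {
  expect_identical(makeVesselPhantom(11, nBranches = 4),
                   makeVesselPhantom(11, nBranches = 4))
  expect_false(identical(makeVesselPhantom(11, nBranches = 4)@centers,
                         makeVesselPhantom(12, nBranches = 4)@centers))
})

test_that("vessel phantom validates its inputs", {
  expect_error(makeVesselPhantom(1, wavelengths = c(800, 532)), "532")
  expect_error(makeVesselPhantom(1, so2Artery = 1.2), "so2")
  expect_error(makeVesselPhantom(1, nBranches = 0), "nBranches")
})
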