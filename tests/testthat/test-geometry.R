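test_that("raster geometry lays out the scan grid correctly", {
  g <- makeRasterGeometry(128, 128, 100e-6, 10)
  pos <- scanPositions(g)
  expect_equal(nrow(pos), 16384L)
  expect_equal(diff(range(pos[, 1])), 12.7e-3)
  expect_equal(diff(range(pos[, 2])), 12.7e-3)
  expect_true(all(pos[, 3] == 0))

  g1 <- makeRasterGeometry(1, 1, 1e-4, 10)
  expect_equal(unname(scanPositions(g1)), matrix(c(0, 0, 0), 1))

  g2 <- makeRasterGeometry(3, 2, 1e-3, 10)
  pos2 <- scanPositions(g2)
  expect_equal(nrow(pos2), 6L)
  # point [2, 1] (0-based) = origin + (2 mm, 1 mm, 0); x varies fastest
  expect_equal(unname(pos2[1 + 2 + 3 * 1, ]), c(2e-3, 1e-3, 0))

  g3 <- makeRasterGeometry(2, 2, 5e-4, 10, origin = c(1e-3, -1e-3, 2e-3))
  expect_equal(unname(scanPositions(g3)[4, ]), c(1.5e-3, -0.5e-3, 2e-3))
})

test_that("invalid geometry arguments are rejected", {
  expect_error(makeRasterGeometry(0, 4, 1e-4, 10), "nx and ny")
  expect_error(makeRasterGeometry(4, 4, -1e-4, 10), "pitch")
  expect_error(makeRasterGeometry(4, 4, 1e-4, 0), "repRate")
})

test_that("acquisition time is points over repetition rate", {
  g <- makeRasterGeometry(128, 128, 100e-6, 10)
  expect_equal(acquisitionTime(g), 1638.4)
  expect_equal(acquisitionTime(g, whole = TRUE), 1639)
  expect_equal(acquisitionTime(makeRasterGeometry(1, 1, 1e-4, 10)), 0.1)
  # a 1 kHz laser brings a 10x10 scan to a tenth of a second
  expect_equal(acquisitionTime(makeRasterGeometry(10, 10, 1e-4, 1000)), 0.1)
})
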