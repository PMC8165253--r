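# Shared, lazily computed end-to-end fixtures (each is simulated once per
# test run and reused across test files).

# Wire-phantom resolution experiment at the standard desk-scale conditions.
wireExperimentCache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(wireResolutionExperiment(seed = 1L))
    cache
  }
})

# Dual-wavelength vessel pipeline: one artery tree (so2 0.95) and one vein
# tree (so2 0.65), simulated at the isosbestic 800 nm and at 1,064 nm,
# reconstructed and envelope-detected on a common grid.
vesselPipelineCache <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    phantom <- makeVesselPhantom(42L, nBranches = 2L, totalHb = 50)
    geometry <- makeRasterGeometry(24, 24, 150e-6, 10,
                                   origin = c(-1.725e-3, -1.725e-3, 0))
    sensor <- makeSensorModel()
    grid <- makeReconGrid(c(51L, 51L, 54L), 60e-6, c(-1.5e-3, -1.5e-3, 1e-3))
    sos <- makeSOSModel(1500)
    vols <- lapply(c("800" = 800, "1064" = 1064), function(wl) {
      ss <- simulateSignals(phantom, geometry, sensor, fs = 125e6,
                            nSamples = 560L, wavelength = wl,
                            noiseSeed = 42L + round(wl))
      suppressMessages(hilbertEnvelopeZ(ubpReconstruct(ss, sos, grid)))
    })
    cache <<- list(phantom = phantom, grid = grid,
                   vol800 = vols[["800"]], vol1064 = vols[["1064"]])
    cache
  }
})

# Small point-source round trip used for localization and linearity checks.
pointSourceRecon <- function(depth = 3e-3, amplitude = 1, noiseSeed = NULL,
                             sosModel = makeSOSModel(1500),
                             voxel = 50e-6) {
  phantom <- makeAbsorberPhantom(rbind(c(0, 0, depth)), 100e-6,
                                 setNames(amplitude, "800"))
  geometry <- makeRasterGeometry(32, 32, 100e-6, 10,
                                 origin = c(-1.55e-3, -1.55e-3, 0))
  ss <- simulateSignals(phantom, geometry, makeSensorModel(), fs = 125e6,
                        nSamples = 480L, wavelength = 800,
                        noiseSeed = noiseSeed)
  grid <- makeReconGrid(c(21L, 21L, 41L), voxel,
                        c(-10 * voxel, -10 * voxel, depth - 20 * voxel))
  list(signals = ss, grid = grid,
       volume = suppressMessages(ubpReconstruct(ss, sosModel, grid)))
}

randomSOSModel <- function() {
  makeSOSModel(runif(1, 1400, 1550),
               ellipsoidCenter = runif(3, -2e-3, 2e-3) + c(0, 0, 6e-3),
               ellipsoidSemiAxes = runif(3, 0.5e-3, 4e-3),
               innerSOS = runif(1, 1480, 1650))
}
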