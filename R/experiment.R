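#' Scaled-down wire-phantom resolution experiment
#'
#' End-to-end resolution study mirroring the bench protocol at desk scale:
#' thin wires at graded depths are scanned with a planar raster, the records
#' are reconstructed by universal back projection, envelope-detected along z
#' and fitted with Gaussians to estimate axial and lateral FWHM per depth.
#' The defaults are the study conditions: a 32 x 32-point, 100 um-pitch scan
#' over three 9 um wires at 2, 4 and 6 mm depth, the packaged 23 MHz ringing
#' sensor, 65.8 Pa noise (seeded), 125 MS/s sampling and a 20 um voxel grid.
#' The wire amplitude (5e5 pressure-generating units, i.e. peak signals tens
#' of times the noise floor) reflects the strong optical contrast of
#' tungsten wire targets.
#'
#' @param seed integer seed for the noise stream.
#' @param depths wire depths, metres.
#' @param nx,ny,pitch scan grid (see [makeRasterGeometry()]).
#' @param fs,nSamples sampling rate (Hz) and record length.
#' @param amplitude absorbed-energy amplitude per wire sphere.
#' @param voxel reconstruction voxel size, metres.
#' @param noise logical; `FALSE` for a noise-free run.
#' @param sensor a [SensorModel-class]; default [makeSensorModel()].
#' @return A list with `report` (a [ResolutionReport-class]), `volume` (the
#'   envelope [ReconVolume-class]), `signals` and `phantom`.
#' @examples
#' \donttest{
#' res <- wireResolutionExperiment(seed = 1)
#' res$report
#' }
#' @export
wireResolutionExperiment <- function(seed = 1L, depths = c(2e-3, 4e-3, 6e-3),
                                     nx = 32L, ny = 32L, pitch = 100e-6,
                                     fs = 125e6, nSamples = 720L,
                                     amplitude = 5e5, voxel = 20e-6,
                                     noise = TRUE,
                                     sensor = makeSensorModel()) {
  phantom <- makeWirePhantom(length(depths), 9e-6, depths, sos = 1500,
                             yLength = 2e-3, amplitude = amplitude)
  geometry <- makeRasterGeometry(nx, ny, pitch, 10,
                                 origin = c(-(nx - 1) * pitch / 2,
                                            -(ny - 1) * pitch / 2, 0))
  signals <- simulateSignals(phantom, geometry, sensor, fs = fs,
                             nSamples = nSamples, wavelength = 800,
                             noiseSeed = if (noise) seed else NULL)
  zmin <- max(min(depths) - 0.5e-3, voxel)
  zmax <- max(depths) + 0.5e-3
  grid <- makeReconGrid(c(round(2e-3 / voxel) + 1L, round(0.4e-3 / voxel) + 1L,
                          round((zmax - zmin) / voxel) + 1L),
                        voxel, c(-1e-3, -0.2e-3, zmin))
  vol <- hilbertEnvelopeZ(ubpReconstruct(signals, makeSOSModel(1500), grid))
  report <- estimateResolution(vol, cbind(0, 0, depths))
  list(report = report, volume = vol, signals = signals, phantom = phantom)
}
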