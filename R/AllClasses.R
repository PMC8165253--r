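#' @import methods
#' @importFrom stats fft mvfft rnorm runif sd approx coef predict setNames residuals
#' @importFrom utils packageVersion modifyList
#' @useDynLib PAmeso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("integerOrNA", c("integer", "logical"))

#' Planar raster-scan geometry
#'
#' Detector positions of a planar raster scan: an `nx` by `ny` grid of scan
#' points with constant pitch, all lying in the plane `z = origin[3]`.
#' Point `[i, j]` (0-based) sits at `origin + (i * pitch, j * pitch, 0)`.
#'
#' @slot nx,ny integer scan-point counts along x and y (>= 1).
#' @slot pitch numeric, distance between adjacent scan points in metres.
#' @slot origin numeric length-3, position of scan point `[0, 0]` in metres;
#'   the third component is the detector-plane coordinate.
#' @slot repRate numeric, laser pulse repetition rate in Hz.
#' @seealso [makeRasterGeometry()], [scanPositions()], [acquisitionTime()]
#' @export
setClass("ScanGeometry",
  representation(nx = "integer", ny = "integer", pitch = "numeric",
                 origin = "numeric", repRate = "numeric"))

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (length(object@nx) != 1L || is.na(object@nx) || object@nx < 1L)
    msg <- c(msg, "nx must be a single integer >= 1")
  if (length(object@ny) != 1L || is.na(object@ny) || object@ny < 1L)
    msg <- c(msg, "ny must be a single integer >= 1")
  if (length(object@pitch) != 1L || !is.finite(object@pitch) || object@pitch <= 0)
    msg <- c(msg, "pitch must be a single positive number (metres)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite 3-vector (metres)")
  if (length(object@repRate) != 1L || !is.finite(object@repRate) || object@repRate <= 0)
    msg <- c(msg, "repRate must be a single positive number (Hz)")
  if (length(msg)) msg else TRUE
})

#' Sphere-based absorber phantom
#'
#' A collection of spherical absorbers embedded in a homogeneous acoustic
#' medium. Wires are represented as dense chains of overlapping spheres;
#' vessels as sphere chains along branching centrelines. Each absorber
#' carries one absorbed-energy amplitude per excitation wavelength
#' (arbitrary pressure-generating units).
#'
#' @slot centers numeric n-by-3 matrix of sphere centres (metres).
#' @slot radii numeric vector of sphere radii (metres, > 0).
#' @slot amplitudes numeric n-by-w matrix of per-wavelength amplitudes
#'   (>= 0); column names are wavelengths in nm.
#' @slot labels character vector of class tags (e.g. "artery", "vein",
#'   "wire1").
#' @slot so2 numeric vector of oxygen-saturation fractions in `[0, 1]`,
#'   `NA` where not applicable.
#' @slot mediumSOS numeric, speed of sound of the medium (m/s).
#' @slot name character phantom name.
#' @seealso [makeWirePhantom()], [makeVesselPhantom()], [simulateSignals()]
#' @export
setClass("AbsorberPhantom",
  representation(centers = "matrix", radii = "numeric", amplitudes = "matrix",
                 labels = "character", so2 = "numeric",
                 mediumSOS = "numeric", name = "character"))

setValidity("AbsorberPhantom", function(object) {
  n <- nrow(object@centers)
  msg <- character()
  if (ncol(object@centers) != 3L && n > 0L)
    msg <- c(msg, "centers must be an n-by-3 matrix")
  if (length(object@radii) != n) msg <- c(msg, "radii length must match centers")
  if (n > 0L && any(object@radii <= 0)) msg <- c(msg, "all radii must be > 0")
  if (nrow(object@amplitudes) != n)
    msg <- c(msg, "amplitudes must have one row per absorber")
  if (n > 0L && ncol(object@amplitudes) >= 1L && any(object@amplitudes < 0))
    msg <- c(msg, "amplitudes must be >= 0")
  if (n > 0L && is.null(colnames(object@amplitudes)))
    msg <- c(msg, "amplitude columns must be named by wavelength (nm)")
  if (length(object@labels) != n) msg <- c(msg, "labels length must match centers")
  if (length(object@so2) != n) msg <- c(msg, "so2 length must match centers")
  if (any(!is.na(object@so2) & (object@so2 < 0 | object@so2 > 1)))
    msg <- c(msg, "so2 must lie in [0, 1] where present")
  if (length(object@mediumSOS) != 1L || object@mediumSOS <= 0)
    msg <- c(msg, "mediumSOS must be a single positive number (m/s)")
  if (length(msg)) msg else TRUE
})

#' Ultrasound sensor model
#'
#' Fabry-Perot style wide-band sensor: a sampled impulse-response kernel, a
#' design -3 dB bandwidth, an angular directivity function (scalar gain per
#' incidence angle) and a full-band noise-equivalent pressure.
#'
#' @slot impulseResponse numeric sampled kernel (unitless gain vs time).
#' @slot center integer, index (1-based) of the kernel sample at time zero;
#'   convolution is aligned on this sample so arrival times are preserved.
#' @slot fs numeric sampling rate of the kernel (Hz), must exceed
#'   `2 * bw3db`.
#' @slot bw3db numeric design -3 dB (amplitude) bandwidth in Hz.
#' @slot directivity function mapping incidence angle in degrees
#'   (-90..90) to a gain in `[0, 1]` with `directivity(0) == 1`.
#' @slot nep numeric noise-equivalent pressure in Pa over the full band.
#' @seealso [makeSensorModel()], [frequencyResponse()]
#' @export
setClass("SensorModel",
  representation(impulseResponse = "numeric", center = "integer",
                 fs = "numeric", bw3db = "numeric",
                 directivity = "function", nep = "numeric"))

setValidity("SensorModel", function(object) {
  msg <- character()
  if (!length(object@impulseResponse) || any(!is.finite(object@impulseResponse)))
    msg <- c(msg, "impulseResponse must be finite and non-empty")
  if (object@center < 1L || object@center > length(object@impulseResponse))
    msg <- c(msg, "center must index into impulseResponse")
  if (object@fs <= 2 * object@bw3db)
    msg <- c(msg, "fs must exceed twice the design bandwidth")
  if (abs(object@directivity(0) - 1) > 1e-9)
    msg <- c(msg, "directivity(0) must equal 1")
  if (object@nep < 0) msg <- c(msg, "nep must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Raster-scan signal set
#'
#' Time-series pressure records on the scan grid: a `[nx, ny, nt]` array of
#' pressure in Pa with sampling metadata and the generating geometry.
#'
#' @slot data numeric array `[nx, ny, nt]`, pressure in Pa.
#' @slot fs numeric sampling rate (Hz).
#' @slot t0 numeric, time of the first sample relative to the laser pulse (s).
#' @slot geometry a [ScanGeometry-class].
#' @slot wavelength numeric excitation wavelength in nm.
#' @slot seed integer noise seed or `NA` if noise was off.
#' @seealso [simulateSignals()], [ubpReconstruct()], [writeSignalSet()]
#' @export
setClass("SignalSet",
  representation(data = "array", fs = "numeric", t0 = "numeric",
                 geometry = "ScanGeometry", wavelength = "numeric",
                 seed = "integerOrNA"))

setValidity("SignalSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-axis [nx, ny, nt] array")
  else if (d[1] != object@geometry@nx || d[2] != object@geometry@ny)
    msg <- c(msg, "data dimensions must match the scan geometry")
  if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Speed-of-sound model
#'
#' A homogeneous background speed of sound, optionally with one axis-aligned
#' ellipsoid of different (typically higher) speed, modelling e.g. the head
#' region. Time of flight through this model is computed analytically on
#' straight rays (no refraction).
#'
#' @slot backgroundSOS numeric background speed (m/s).
#' @slot ellipsoid either `NULL` (homogeneous medium) or a list with
#'   elements `center` (3-vector, m), `semiAxes` (3-vector, m, > 0) and
#'   `innerSOS` (m/s).
#' @seealso [makeSOSModel()], [timeOfFlight()], [ubpReconstruct()]
#' @export
setClass("SOSModel",
  representation(backgroundSOS = "numeric", ellipsoid = "ANY"))

setValidity("SOSModel", function(object) {
  msg <- character()
  if (length(object@backgroundSOS) != 1L || object@backgroundSOS <= 0)
    msg <- c(msg, "backgroundSOS must be a single positive number")
  e <- object@ellipsoid
  if (!is.null(e)) {
    if (!is.list(e) || !all(c("center", "semiAxes", "innerSOS") %in% names(e)))
      msg <- c(msg, "ellipsoid needs center, semiAxes, innerSOS")
    else {
      if (length(e$center) != 3L) msg <- c(msg, "ellipsoid center must be a 3-vector")
      if (length(e$semiAxes) != 3L || any(e$semiAxes <= 0))
        msg <- c(msg, "ellipsoid semiAxes must be a positive 3-vector")
      if (length(e$innerSOS) != 1L || e$innerSOS <= 0)
        msg <- c(msg, "innerSOS must be a single positive number")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Reconstruction voxel grid
#'
#' A regular axis-aligned 3D voxel grid. Voxel `[i, j, k]` (0-based) is
#' centred at `origin + voxel * (i, j, k)`.
#'
#' @slot shape integer length-3, voxel counts along x, y, z.
#' @slot voxel numeric voxel edge length in metres (isotropic).
#' @slot origin numeric length-3, centre of voxel `[0, 0, 0]` in metres.
#' @seealso [makeReconGrid()], [ubpReconstruct()]
#' @export
setClass("ReconGrid",
  representation(shape = "integer", voxel = "numeric", origin = "numeric"))

setValidity("ReconGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive voxel counts")
  if (length(object@voxel) != 1L || object@voxel <= 0)
    msg <- c(msg, "voxel must be a single positive number (metres)")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must be a 3-vector")
  if (length(msg)) msg else TRUE
})

#' Reconstructed photoacoustic volume
#'
#' A 3D voxel image of reconstructed photoacoustic amplitude (arbitrary
#' units). Signed straight out of back projection; non-negative once the
#' Hilbert envelope has been applied.
#'
#' @slot grid a [ReconGrid-class].
#' @slot values numeric array matching `shape(grid)`.
#' @slot wavelength numeric excitation wavelength in nm, or `NA`.
#' @slot envelopeApplied logical, whether envelope detection was applied.
#' @seealso [ubpReconstruct()], [hilbertEnvelopeZ()], [writeVolume()]
#' @export
setClass("ReconVolume",
  representation(grid = "ReconGrid", values = "array",
                 wavelength = "numeric", envelopeApplied = "logical"))

setValidity("ReconVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values dimensions must match grid shape")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (isTRUE(object@envelopeApplied) && any(object@values < 0))
    msg <- c(msg, "envelope volumes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Sensor frequency response
#'
#' Magnitude spectrum of a sensor waveform, normalised to its peak, with the
#' -3 dB (amplitude) bandwidth read off by linear interpolation.
#'
#' @slot freqs numeric frequency grid in Hz.
#' @slot magnitudeDB numeric dB relative to the spectral peak (<= 0).
#' @slot bw3db numeric, lowest frequency above the peak where the magnitude
#'   first crosses -3 dB.
#' @seealso [frequencyResponse()]
#' @export
setClass("FrequencyResponse",
  representation(freqs = "numeric", magnitudeDB = "numeric", bw3db = "numeric"))

setValidity("FrequencyResponse", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@magnitudeDB))
    msg <- c(msg, "freqs and magnitudeDB must have equal length")
  if (any(object@magnitudeDB > 1e-9))
    msg <- c(msg, "magnitudeDB must be <= 0 (normalised to peak)")
  if (length(msg)) msg else TRUE
})

#' Angular directivity map
#'
#' Per-angle magnitude spectra of a goniometric sweep, normalised per
#' frequency to the peak gain over angles, plus the angular coverage (widest
#' contiguous angle span with gain above a threshold across a stated band).
#'
#' @slot angles numeric angles in degrees, strictly increasing in
#'   `[-90, 90]`.
#' @slot freqs numeric frequency grid in Hz.
#' @slot gain numeric matrix `[angle, freq]` in `[0, 1]`.
#' @slot coverage numeric angular coverage in degrees.
#' @slot threshold numeric gain threshold used for coverage (default 0.5).
#' @seealso [directivityMap()]
#' @export
setClass("DirectivityMap",
  representation(angles = "numeric", freqs = "numeric", gain = "matrix",
                 coverage = "numeric", threshold = "numeric"))

setValidity("DirectivityMap", function(object) {
  msg <- character()
  if (nrow(object@gain) != length(object@angles) ||
      ncol(object@gain) != length(object@freqs))
    msg <- c(msg, "gain must be [angle, freq]")
  if (any(object@gain < -1e-12) || any(object@gain > 1 + 1e-9))
    msg <- c(msg, "gains must lie in [0, 1] after normalisation")
  if (length(msg)) msg else TRUE
})

#' Wire-phantom resolution report
#'
#' Per-wire axial and lateral full-width-at-half-maximum estimates from
#' Gaussian line-spread-function fits, plus a linear depth trend of the
#' lateral width. `FWHM = 2 * sqrt(2 * log(2)) * sigma` of the fitted
#' Gaussian.
#'
#' @slot wires data.frame with columns `depth`, `axialFWHM`, `lateralFWHM`,
#'   `r2Axial`, `r2Lateral`, `usable` (all lengths in metres).
#' @slot lateralTrend numeric length-2, intercept and slope of lateral FWHM
#'   vs depth over usable wires.
#' @seealso [estimateResolution()]
#' @export
setClass("ResolutionReport",
  representation(wires = "data.frame", lateralTrend = "numeric"))

#' Vessel segmentation
#'
#' Integer label volume (0 = background) from hysteresis thresholding with
#' a minimum-size filter, labels sorted by decreasing component size, plus a
#' per-label summary table.
#'
#' @slot labels integer array on the reconstruction grid.
#' @slot grid a [ReconGrid-class].
#' @slot table data.frame with columns `label` and `voxelCount`.
#' @seealso [segmentVessels()], [meanPAA()]
#' @export
setClass("VesselSegmentation",
  representation(labels = "array", grid = "ReconGrid", table = "data.frame"))

setValidity("VesselSegmentation", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), as.integer(object@grid@shape)))
    msg <- c(msg, "label dimensions must match grid shape")
  k <- max(0L, object@labels)
  if (k > 0L && !setequal(setdiff(unique(as.vector(object@labels)), 0L), seq_len(k)))
    msg <- c(msg, "labels must be contiguous positive integers")
  if (length(msg)) msg else TRUE
})

#' Relative optical fluence map
#'
#' Unitless relative fluence on a reconstruction grid, 1 at and above the
#' tissue surface and decaying with depth below it following the diffusion
#' approximation (effective attenuation `mu_eff`).
#'
#' @slot values numeric array in `(0, 1]` matching the grid shape.
#' @slot grid a [ReconGrid-class].
#' @slot wavelength numeric nm or `NA`.
#' @slot muA,muSPrime numeric absorption and reduced scattering
#'   coefficients in 1/m.
#' @seealso [computeFluence()], [fluenceCompensate()]
#' @export
setClass("FluenceMap",
  representation(values = "array", grid = "ReconGrid", wavelength = "numeric",
                 muA = "numeric", muSPrime = "numeric"))

setValidity("FluenceMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values dimensions must match grid shape")
  if (any(object@values <= 0) || any(object@values > 1 + 1e-12))
    msg <- c(msg, "fluence values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
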