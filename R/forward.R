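#' Pressure waveform of a uniformly heated sphere
#'
#' Closed-form N-wave of a uniformly heated sphere of radius `a` observed at
#' distance `d`: `p(t) = A (d - c t) / (2 d)` for `|d - c t| < a` and zero
#' otherwise -- a bipolar pulse of peak magnitude `A a / (2 d)` centred on
#' the arrival time `d / c` that integrates to zero over its support.
#'
#' @param center sphere centre, metres (3-vector).
#' @param radius sphere radius, metres.
#' @param amplitude absorbed-energy amplitude `A` at the excitation
#'   wavelength (arbitrary pressure-generating units).
#' @param detector detector position, metres (3-vector); must lie outside
#'   the sphere.
#' @param times sample times, seconds.
#' @param sos speed of sound, m/s.
#' @return Numeric pressure series, one value per time.
#' @examples
#' ts <- seq(1.9e-6, 2.1e-6, by = 1e-9)
#' p <- spherePressureWaveform(c(0, 0, 3e-3), 50e-6, 1, c(0, 0, 0), ts, 1500)
#' max(abs(p))   # ~ radius / (2 * 3e-3)
#' @export
spherePressureWaveform <- function(center, radius, amplitude, detector,
                                   times, sos = 1500) {
  d <- sqrt(sum((as.numeric(center) - as.numeric(detector))^2))
  if (d <= radius) stop("detector lies inside the sphere")
  arg <- d - sos * times
  ifelse(abs(arg) < radius, amplitude * arg / (2 * d), 0)
}

# Sample a directivity function onto a regular 0..90 deg table for the C++
# forward projector (incidence is symmetric about the detector normal).
.directivityTable <- function(directivity, step = 0.25) {
  ang <- seq(0, 90, by = step)
  g <- vapply(ang, function(a) as.numeric(directivity(a)), numeric(1))
  list(table = pmin(pmax(g, 0), 1), step = step)
}

# FFT convolution of each row of x (time along columns) with kernel h,
# aligned on the kernel's time-zero sample so arrival times are preserved.
.convolveRows <- function(x, h, center) {
  nt <- ncol(x); L <- length(h)
  nfft <- 2L^ceiling(log2(nt + L))
  H <- fft(c(h, rep(0, nfft - L)))
  X <- mvfft(rbind(t(x), matrix(0, nfft - nt, nrow(x))))
  z <- Re(mvfft(X * H, inverse = TRUE)) / nfft
  t(z[center:(center + nt - 1L), , drop = FALSE])
}

#' Simulate raster-scan photoacoustic signals
#'
#' Forward model of the planar-scan acquisition: for every scan point, the
#' N-waves of all phantom spheres are summed (attenuated by the sensor's
#' directivity at the incidence angle between the detector normal and the
#' source direction), convolved with the sensor impulse response, and
#' optionally contaminated with zero-mean white Gaussian noise of standard
#' deviation equal to the sensor NEP. The model is linear in the phantom
#' amplitudes and deterministic for a fixed noise seed.
#'
#' Each raw sample is the exact average of the closed-form N-wave over its
#' sample bin (computed from the antiderivative) rather than a pointwise
#' evaluation: the micrometre-scale spheres used for wires have support
#' shorter than one sample period, and bin averaging keeps their energy on
#' the grid instead of aliasing. Set `binAverage = FALSE` for strict
#' pointwise sampling.
#'
#' @param phantom an [AbsorberPhantom-class].
#' @param geometry a [ScanGeometry-class].
#' @param sensor a [SensorModel-class]; its kernel is resampled if its rate
#'   differs from `fs`.
#' @param fs sampling rate, Hz; must be at least `2.5 *` the sensor design
#'   bandwidth.
#' @param nSamples number of time samples per record.
#' @param wavelength excitation wavelength, nm; must be tabulated in the
#'   phantom amplitudes.
#' @param noiseSeed integer seed for the noise stream, or `NULL` for a
#'   noise-free simulation.
#' @param t0 time of the first sample relative to the laser pulse, seconds.
#' @param binAverage logical, see Details.
#' @return A [SignalSet-class] with data `[nx, ny, nSamples]` in Pa.
#' @examples
#' ph <- makeAbsorberPhantom(rbind(c(0, 0, 2e-3)), 100e-6, c("800" = 1))
#' g <- makeRasterGeometry(4, 4, 200e-6, 10, origin = c(-3e-4, -3e-4, 0))
#' ss <- simulateSignals(ph, g, makeSensorModel(), 125e6, 400, 800)
#' @export
simulateSignals <- function(phantom, geometry, sensor, fs = sampleRate(sensor),
                            nSamples, wavelength, noiseSeed = NULL, t0 = 0,
                            binAverage = TRUE) {
  stopifnot(is(phantom, "AbsorberPhantom"), is(geometry, "ScanGeometry"),
            is(sensor, "SensorModel"))
  if (fs < 2.5 * sensor@bw3db)
    stop("fs must be at least 2.5x the sensor design bandwidth")
  nx <- geometry@nx; ny <- geometry@ny
  n <- nAbsorbers(phantom)
  if (n == 0L) {
    raw <- matrix(0, nx * ny, nSamples)
  } else {
    wl <- as.character(wavelength)
    if (!wl %in% colnames(phantom@amplitudes))
      stop("wavelength ", wl, " nm is not tabulated in the phantom")
    dt <- .directivityTable(sensor@directivity)
    raw <- .cppForwardProject(phantom@centers, phantom@radii,
                              phantom@amplitudes[, wl], scanPositions(geometry),
                              dt$table, dt$step, phantom@mediumSOS, fs, t0,
                              as.integer(nSamples), isTRUE(binAverage))
  }
  h <- sensor@impulseResponse
  center <- sensor@center
  if (abs(sensor@fs - fs) > 1e-6 * fs) {
    tk <- (seq_along(h) - center) / sensor@fs
    tq <- seq(min(tk), max(tk), by = 1 / fs)
    h <- approx(tk, h, xout = tq, rule = 2)$y
    center <- which.min(abs(tq))
  }
  sig <- .convolveRows(raw, h, center)
  if (!is.null(noiseSeed)) {
    noise <- .withSeed(noiseSeed,
                       rnorm(length(sig), mean = 0, sd = sensor@nep))
    sig <- sig + noise
    seed <- as.integer(noiseSeed)
  } else seed <- NA
  new("SignalSet", data = array(sig, dim = c(nx, ny, nSamples)), fs = fs,
      t0 = t0, geometry = geometry, wavelength = as.numeric(wavelength),
      seed = seed)
}
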