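#' Frequency response of a sensor waveform
#'
#' Magnitude spectrum of the FFT of a temporal response, normalised to its
#' peak, with the -3 dB (amplitude) bandwidth read off as the first crossing
#' above the spectral peak, linearly interpolated between frequency bins.
#' Records are short pulses, so no window is applied (rectangular window).
#' If the spectrum never falls 3 dB below its peak (e.g. a discrete delta),
#' the bandwidth is the Nyquist frequency.
#'
#' @param waveform numeric pressure series (finite, not all zero).
#' @param fs sampling rate, Hz.
#' @param nfft FFT length after zero padding; default the larger of 4096 and
#'   the next power of two above the record length.
#' @return A [FrequencyResponse-class].
#' @examples
#' # Gaussian pulse: closed-form -3 dB point sqrt(log(2)) / (2*pi*sigma)
#' fs <- 125e6; t <- (0:511 - 256) / fs; sig <- 20e-9
#' fr <- frequencyResponse(exp(-t^2 / (2 * sig^2)), fs)
#' c(bandwidth3dB(fr), sqrt(log(2)) / (2 * pi * sig))
#' @export
frequencyResponse <- function(waveform, fs, nfft = NULL) {
  if (any(!is.finite(waveform))) stop("waveform must be finite")
  if (all(waveform == 0)) stop("undefined response: waveform is all zero")
  sp <- .magSpectrum(waveform, fs, nfft)
  magDB <- 20 * log10(sp$mag / max(sp$mag))
  new("FrequencyResponse", freqs = sp$freqs, magnitudeDB = pmin(magDB, 0),
      bw3db = .bw3dbCrossing(sp$freqs, sp$mag))
}

#' Angular directivity map from a goniometric sweep
#'
#' Stacks per-angle magnitude spectra of a sweep of recorded waveforms
#' (one per incidence angle) into a `[angle, freq]` gain map, normalised per
#' frequency to the peak over angles (directivity is relative gain vs
#' angle), and reports the angular coverage: the widest contiguous
#' angle span over which the gain stays at or above `threshold` at every
#' frequency of the stated band. The default threshold of 0.5 is the -6 dB
#' power point; the bench sweep of the Fabry-Perot sensor uses 181 waveforms
#' from -90 to 90 degrees at 1 degree steps.
#'
#' @param sweep list of waveforms, or a matrix with one row per angle.
#' @param angles numeric angles in degrees, strictly increasing within
#'   `[-90, 90]`, one per waveform.
#' @param fs sampling rate, Hz.
#' @param band numeric length-2 frequency band (Hz) over which coverage is
#'   assessed; default 1 MHz to 23 MHz.
#' @param threshold gain threshold for coverage (default 0.5).
#' @param nfft FFT length (zero padded).
#' @return A [DirectivityMap-class].
#' @export
directivityMap <- function(sweep, angles, fs, band = c(1e6, 23e6),
                           threshold = 0.5, nfft = 512L) {
  if (is.matrix(sweep)) sweep <- asplit(sweep, 1)
  if (length(sweep) != length(angles))
    stop("one waveform per angle is required")
  if (any(duplicated(angles))) stop("duplicate angles")
  if (is.unsorted(angles, strictly = TRUE)) stop("angles must be strictly increasing")
  if (any(angles < -90 | angles > 90)) stop("angles must lie in [-90, 90]")
  spec <- vapply(sweep, function(w) .magSpectrum(w, fs, nfft)$mag,
                 numeric(nfft %/% 2L + 1L))
  freqs <- (seq_len(nfft %/% 2L + 1L) - 1L) * fs / nfft
  # directivity is relative gain vs angle at each frequency: normalise each
  # frequency column to its own peak over angles
  colMax <- apply(spec, 1L, max)
  gain <- t(spec / ifelse(colMax > 0, colMax, 1))
  inBand <- freqs >= band[1] & freqs <= band[2]
  ok <- apply(gain[, inBand, drop = FALSE] >= threshold, 1L, all)
  coverage <- 0
  if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    spans <- ifelse(r$values, angles[ends] - angles[starts], 0)
    coverage <- max(spans)
  }
  new("DirectivityMap", angles = as.numeric(angles), freqs = freqs,
      gain = pmin(gain, 1), coverage = coverage, threshold = threshold)
}

#' Noise-equivalent pressure from a noise record
#'
#' Full-band NEP as the standard deviation of a calibrated signal-free
#' record. The bench value for the packaged sensor is 65.8 Pa over the full
#' bandwidth.
#'
#' @param noiseRecord numeric record containing no signal epoch (raw units).
#' @param calibrationGain Pa per raw unit (default 1, record already in Pa).
#' @return NEP in Pa.
#' @examples
#' set.seed(1)
#' estimateNEP(rnorm(1e5, sd = 65.8))   # ~65.8
#' @export
estimateNEP <- function(noiseRecord, calibrationGain = 1) {
  if (length(noiseRecord) < 100L)
    stop("insufficient data: need at least 100 samples")
  if (all(noiseRecord == 0)) return(0)
  calibrationGain * sd(noiseRecord)
}
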