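#' Accessor generics
#'
#' Small accessor generics used across the package so that slot layout stays
#' an implementation detail.
#'
#' @param object an object of one of the package classes.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scanPositions", function(object) standardGeneric("scanPositions"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))

#' @rdname accessors
#' @export
setGeneric("volumeValues", function(object) standardGeneric("volumeValues"))

#' @rdname accessors
#' @export
setGeneric("reconGrid", function(object) standardGeneric("reconGrid"))

#' @rdname accessors
#' @export
setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))

#' @rdname accessors
#' @export
setGeneric("bandwidth3dB", function(object) standardGeneric("bandwidth3dB"))

#' @rdname accessors
#' @export
setGeneric("nAbsorbers", function(object) standardGeneric("nAbsorbers"))

#' @rdname accessors
#' @export
setMethod("sampleRate", "SignalSet", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("sampleRate", "SensorModel", function(object) object@fs)

#' @rdname accessors
#' @export
setMethod("signalData", "SignalSet", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("volumeValues", "ReconVolume", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("volumeValues", "FluenceMap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("reconGrid", "ReconVolume", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("reconGrid", "VesselSegmentation", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("reconGrid", "FluenceMap", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("labelVolume", "VesselSegmentation", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("bandwidth3dB", "FrequencyResponse", function(object) object@bw3db)

#' @rdname accessors
#' @export
setMethod("bandwidth3dB", "SensorModel", function(object) object@bw3db)

#' @rdname accessors
#' @export
setMethod("nAbsorbers", "AbsorberPhantom", function(object) nrow(object@centers))

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %d x %d points, pitch %.3g um, span %.3g x %.3g mm, rep rate %g Hz\n",
              object@nx, object@ny, object@pitch * 1e6,
              (object@nx - 1L) * object@pitch * 1e3,
              (object@ny - 1L) * object@pitch * 1e3, object@repRate))
})

setMethod("show", "AbsorberPhantom", function(object) {
  cat(sprintf("AbsorberPhantom '%s': %d spheres, %d wavelength(s) [%s nm], medium SOS %g m/s\n",
              object@name, nrow(object@centers), ncol(object@amplitudes),
              paste(colnames(object@amplitudes), collapse = ", "),
              object@mediumSOS))
  if (length(object@labels))
    cat("  labels:", paste(utils::head(unique(object@labels), 8), collapse = ", "), "\n")
})

setMethod("show", "SensorModel", function(object) {
  cat(sprintf("SensorModel: %d-sample kernel at %g MS/s, -3 dB bandwidth %.1f MHz, NEP %.1f Pa\n",
              length(object@impulseResponse), object@fs / 1e6,
              object@bw3db / 1e6, object@nep))
})

setMethod("show", "SignalSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("SignalSet: [%d x %d x %d] at %g MS/s, t0 %.3g us, %g nm, noise seed %s\n",
              d[1], d[2], d[3], object@fs / 1e6, object@t0 * 1e6,
              object@wavelength,
              if (is.na(object@seed)) "off" else as.character(object@seed)))
})

setMethod("show", "SOSModel", function(object) {
  if (is.null(object@ellipsoid))
    cat(sprintf("SOSModel: homogeneous, %g m/s\n", object@backgroundSOS))
  else
    cat(sprintf("SOSModel: background %g m/s, ellipsoid (inner %g m/s) at (%s) mm, semi-axes (%s) mm\n",
                object@backgroundSOS, object@ellipsoid$innerSOS,
                paste(sprintf("%.2f", object@ellipsoid$center * 1e3), collapse = ", "),
                paste(sprintf("%.2f", object@ellipsoid$semiAxes * 1e3), collapse = ", ")))
})

setMethod("show", "ReconGrid", function(object) {
  cat(sprintf("ReconGrid: %d x %d x %d voxels of %.3g um\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@voxel * 1e6))
})

setMethod("show", "ReconVolume", function(object) {
  cat(sprintf("ReconVolume: %d x %d x %d, %s, wavelength %s nm, range [%.3g, %.3g]\n",
              dim(object@values)[1], dim(object@values)[2], dim(object@values)[3],
              if (object@envelopeApplied) "envelope" else "signed",
              if (is.na(object@wavelength)) "-" else as.character(object@wavelength),
              min(object@values), max(object@values)))
})

setMethod("show", "FrequencyResponse", function(object) {
  cat(sprintf("FrequencyResponse: %d bins to %.1f MHz, -3 dB bandwidth %.2f MHz\n",
              length(object@freqs), max(object@freqs) / 1e6, object@bw3db / 1e6))
})

setMethod("show", "DirectivityMap", function(object) {
  cat(sprintf("DirectivityMap: %d angles [%g..%g deg] x %d freqs, coverage %.1f deg at gain >= %.2f\n",
              length(object@angles), min(object@angles), max(object@angles),
              length(object@freqs), object@coverage, object@threshold))
})

setMethod("show", "ResolutionReport", function(object) {
  cat(sprintf("ResolutionReport: %d wires (%d usable)\n",
              nrow(object@wires), sum(object@wires$usable)))
  print(transform(object@wires,
                  depth = depth * 1e6, axialFWHM = axialFWHM * 1e6,
                  lateralFWHM = lateralFWHM * 1e6), digits = 3)
  cat(sprintf("  lateral FWHM trend: %.1f um + %.3f um/um depth\n",
              object@lateralTrend[1] * 1e6, object@lateralTrend[2]))
})

setMethod("show", "VesselSegmentation", function(object) {
  cat(sprintf("VesselSegmentation: %d components on a %d x %d x %d grid\n",
              nrow(object@table), object@grid@shape[1], object@grid@shape[2],
              object@grid@shape[3]))
})

setMethod("show", "FluenceMap", function(object) {
  cat(sprintf("FluenceMap: mu_a %.3g /m, mu_s' %.3g /m, mu_eff %.3g /m, min %.3g\n",
              object@muA, object@muSPrime,
              sqrt(3 * object@muA * (object@muA + object@muSPrime)),
              min(object@values)))
})
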