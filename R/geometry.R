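#' Create a planar raster-scan geometry
#'
#' Build the detector-position grid of a planar raster scan: `nx * ny` points
#' with constant pitch in the plane `z = origin[3]`. The default matches the
#' mesoscope acquisition: a 128 x 128 grid at 100 um pitch scanned at 10 Hz,
#' i.e. 16,384 waveforms spanning 12.7 x 12.7 mm.
#'
#' @param nx,ny number of scan points along x and y (>= 1).
#' @param pitch step size between adjacent points, metres.
#' @param repRate laser pulse repetition rate, Hz (one pulse per point).
#' @param origin position of scan point `[0, 0]`, metres; the z component is
#'   the detector-plane coordinate (z increases with depth into tissue, so
#'   the detector plane is conventionally at z = 0).
#' @return A [ScanGeometry-class] object.
#' @examples
#' g <- makeRasterGeometry(128, 128, 100e-6, 10)
#' nrow(scanPositions(g))   # 16384
#' acquisitionTime(g)       # 1638.4 s
#' @export
makeRasterGeometry <- function(nx, ny, pitch, repRate, origin = c(0, 0, 0)) {
  if (length(nx) != 1L || is.na(nx) || nx < 1 || nx != round(nx) ||
      length(ny) != 1L || is.na(ny) || ny < 1 || ny != round(ny))
    stop("nx and ny must be single integers >= 1")
  if (length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("pitch must be a single positive number (metres)")
  if (length(repRate) != 1L || !is.finite(repRate) || repRate <= 0)
    stop("repRate must be a single positive number (Hz)")
  new("ScanGeometry", nx = as.integer(nx), ny = as.integer(ny),
      pitch = as.numeric(pitch), origin = as.numeric(origin),
      repRate = as.numeric(repRate))
}

#' @describeIn makeRasterGeometry All detector positions as an `(nx*ny) x 3`
#'   matrix in metres, x index varying fastest (column-major over the grid).
#' @param object a [ScanGeometry-class].
#' @export
setMethod("scanPositions", "ScanGeometry", function(object) {
  i <- rep(seq_len(object@nx) - 1L, times = object@ny)
  j <- rep(seq_len(object@ny) - 1L, each = object@nx)
  cbind(x = object@origin[1] + i * object@pitch,
        y = object@origin[2] + j * object@pitch,
        z = rep(object@origin[3], length(i)))
})

#' Acquisition time of a raster scan
#'
#' With one laser pulse per scan point and no averaging, the acquisition
#' time is `nx * ny / repRate` seconds. The mesoscope's 128 x 128 grid at
#' 10 Hz takes 1638.4 s, i.e. 1,639 whole seconds (about 30 min); at a 1 kHz
#' laser the same scan would complete within about 20 s.
#'
#' @param geometry a [ScanGeometry-class].
#' @param whole if `TRUE`, report the ceiling in whole seconds.
#' @return Acquisition time in seconds (real-valued, or integer-valued
#'   ceiling when `whole = TRUE`).
#' @examples
#' acquisitionTime(makeRasterGeometry(128, 128, 100e-6, 10))              # 1638.4
#' acquisitionTime(makeRasterGeometry(128, 128, 100e-6, 10), whole = TRUE) # 1639
#' @export
acquisitionTime <- function(geometry, whole = FALSE) {
  stopifnot(is(geometry, "ScanGeometry"))
  tt <- as.numeric(geometry@nx) * as.numeric(geometry@ny) / geometry@repRate
  if (whole) ceiling(tt) else tt
}
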