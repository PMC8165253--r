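#' Create a reconstruction voxel grid
#'
#' @param shape integer length-3, voxel counts along x, y, z.
#' @param voxel isotropic voxel edge length, metres.
#' @param origin centre of voxel `[0, 0, 0]`, metres.
#' @return A [ReconGrid-class].
#' @examples
#' makeReconGrid(c(64, 64, 128), 50e-6, c(-1.6e-3, -1.6e-3, 1e-3))
#' @export
makeReconGrid <- function(shape, voxel, origin = c(0, 0, 0)) {
  new("ReconGrid", shape = as.integer(shape), voxel = as.numeric(voxel),
      origin = as.numeric(origin))
}

#' @describeIn makeReconGrid Voxel-centre coordinates along one axis
#'   (1 = x, 2 = y, 3 = z), metres.
#' @param grid a [ReconGrid-class].
#' @param axis axis index.
#' @export
gridCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1L) * grid@voxel
}

#' 3D universal back projection
#'
#' Reconstructs the initial pressure distribution from planar raster-scan
#' records with the universal back-projection algorithm: each voxel sums the
#' filtered back-projection term `b(t) = 2 p(t) - 2 t dp/dt`, evaluated at
#' the analytic time of flight from every detector (single or dual speed of
#' sound, see [timeOfFlight()]), weighted by the solid angle each detector
#' cell subtends at the voxel (`cos(theta) * pitch^2 / dist^2`, normalised
#' over the aperture). The time derivative uses central differences and
#' delayed samples are linearly interpolated between the two straddling
#' samples. Times of flight outside the record contribute zero; the
#' truncated fraction is reported as the `"truncFrac"` attribute.
#'
#' The output is signed; envelope detection is an explicit separate stage
#' ([hilbertEnvelopeZ()]).
#'
#' @param signals a [SignalSet-class].
#' @param sosModel an [SOSModel-class].
#' @param grid a [ReconGrid-class].
#' @return A [ReconVolume-class] (signed), with attribute `"truncFrac"` on
#'   the returned object's `values` giving the truncated pair fraction.
#' @examples
#' ## see the package vignette for a forward-then-invert round trip
#' @export
ubpReconstruct <- function(signals, sosModel, grid) {
  stopifnot(is(signals, "SignalSet"), is(sosModel, "SOSModel"),
            is(grid, "ReconGrid"))
  d <- dim(signals@data)
  nDet <- d[1] * d[2]; nt <- d[3]
  p <- matrix(signals@data, nDet, nt)
  fs <- signals@fs
  # central-difference derivative, one-sided at the edges
  dp <- cbind(p[, 2L] - p[, 1L],
              (p[, 3:nt, drop = FALSE] - p[, 1:(nt - 2L), drop = FALSE]) / 2,
              p[, nt] - p[, nt - 1L]) * fs
  tt <- signals@t0 + (seq_len(nt) - 1L) / fs
  b <- 2 * p - 2 * dp * rep(tt, each = nDet)
  e <- sosModel@ellipsoid
  res <- .cppUbp(b, scanPositions(signals@geometry),
                 signals@geometry@pitch, fs, signals@t0, grid@origin,
                 grid@voxel, grid@shape, sosModel@backgroundSOS, !is.null(e),
                 if (is.null(e)) numeric(3) else e$center,
                 if (is.null(e)) rep(1, 3) else e$semiAxes,
                 if (is.null(e)) sosModel@backgroundSOS else e$innerSOS)
  vals <- array(res$values, dim = grid@shape)
  attr(vals, "truncFrac") <- res$truncFrac
  if (res$truncFrac > 0)
    message(sprintf("ubpReconstruct: %.2f%% of voxel/detector pairs outside the record",
                    100 * res$truncFrac))
  new("ReconVolume", grid = grid, values = vals,
      wavelength = signals@wavelength, envelopeApplied = FALSE)
}

#' Hilbert-transform envelope along z
#'
#' Replaces every (x, y) column of a signed reconstruction by the magnitude
#' of its analytic signal along the z axis, eliminating the negative
#' (bipolar) artefact so the volume suits maximum-intensity rendering. The
#' output is non-negative and pointwise dominates the absolute input.
#'
#' @param volume a signed [ReconVolume-class] with at least 4 z samples.
#' @return A [ReconVolume-class] with `envelopeApplied = TRUE`.
#' @export
hilbertEnvelopeZ <- function(volume) {
  stopifnot(is(volume, "ReconVolume"))
  if (volume@envelopeApplied) stop("envelope already applied")
  nz <- dim(volume@values)[3]
  if (nz < 4L) stop("need at least 4 samples along z")
  nx <- dim(volume@values)[1]; ny <- dim(volume@values)[2]
  m <- matrix(aperm(volume@values, c(3, 1, 2)), nrow = nz)
  # analytic-signal weights: keep DC (and Nyquist for even n), double the
  # positive frequencies, zero the negative ones
  w <- numeric(nz)
  if (nz %% 2L == 0L) {
    w[1L] <- 1; w[nz / 2L + 1L] <- 1; w[2:(nz / 2L)] <- 2
  } else {
    w[1L] <- 1; w[2:((nz + 1L) / 2L)] <- 2
  }
  env <- Mod(mvfft(mvfft(m) * w, inverse = TRUE) / nz)
  vals <- aperm(array(env, dim = c(nz, nx, ny)), c(2, 3, 1))
  tf <- attr(volume@values, "truncFrac")
  if (!is.null(tf)) attr(vals, "truncFrac") <- tf
  new("ReconVolume", grid = volume@grid, values = vals,
      wavelength = volume@wavelength, envelopeApplied = TRUE)
}
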