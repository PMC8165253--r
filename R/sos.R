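#' Create a speed-of-sound model
#'
#' Homogeneous background speed, optionally with one axis-aligned ellipsoid
#' of different speed (e.g. the higher-speed head region used for deep
#' reconstructions). Time of flight is computed analytically on straight
#' rays; refraction at the boundary is deliberately not modelled, which is
#' the only reading consistent with an analytic two-speed time of flight.
#'
#' @param backgroundSOS background speed of sound, m/s.
#' @param ellipsoidCenter,ellipsoidSemiAxes ellipsoid centre and semi-axes,
#'   metres (3-vectors); both `NULL` for a homogeneous medium.
#' @param innerSOS speed inside the ellipsoid, m/s.
#' @return An [SOSModel-class].
#' @examples
#' makeSOSModel(1500)
#' makeSOSModel(1500, c(0, 0, 5e-3), c(2e-3, 2e-3, 2e-3), 1540)
#' @export
makeSOSModel <- function(backgroundSOS = 1500, ellipsoidCenter = NULL,
                         ellipsoidSemiAxes = NULL, innerSOS = NULL) {
  ell <- NULL
  if (!is.null(ellipsoidCenter) || !is.null(ellipsoidSemiAxes) ||
      !is.null(innerSOS)) {
    if (is.null(ellipsoidCenter) || is.null(ellipsoidSemiAxes) ||
        is.null(innerSOS))
      stop("ellipsoidCenter, ellipsoidSemiAxes and innerSOS must be given together")
    ell <- list(center = as.numeric(ellipsoidCenter),
                semiAxes = as.numeric(ellipsoidSemiAxes),
                innerSOS = as.numeric(innerSOS))
  }
  new("SOSModel", backgroundSOS = as.numeric(backgroundSOS), ellipsoid = ell)
}

#' Analytic time of flight through a two-speed medium
#'
#' Straight-ray time of flight from detector to voxel. With an ellipsoid,
#' the quadratic for the intersection of the ray with the axis-aligned
#' ellipsoid yields the interior chord length `L_in`, and
#' `TOF = L_in / innerSOS + (L - L_in) / backgroundSOS`; tangent or missing
#' rays have zero interior length. Without an ellipsoid (or when the inner
#' speed equals the background) the homogeneous `distance / backgroundSOS`
#' is returned, identically in both code paths.
#'
#' @param detector detector position(s): 3-vector or n-by-3 matrix, metres.
#' @param voxel voxel position(s): 3-vector or n-by-3 matrix, metres.
#' @param sosModel an [SOSModel-class].
#' @return Time(s) of flight in seconds.
#' @examples
#' timeOfFlight(c(0, 0, 0), c(0, 0, 0.01), makeSOSModel(1500)) * 1e6  # 6.667 us
#' @export
timeOfFlight <- function(detector, voxel, sosModel) {
  stopifnot(is(sosModel, "SOSModel"))
  det <- rbind(detector); vox <- rbind(voxel)
  if (nrow(det) == 1L && nrow(vox) > 1L)
    det <- det[rep(1L, nrow(vox)), , drop = FALSE]
  if (nrow(vox) == 1L && nrow(det) > 1L)
    vox <- vox[rep(1L, nrow(det)), , drop = FALSE]
  if (any(rowSums((det - vox)^2) == 0))
    stop("detector and voxel must differ")
  e <- sosModel@ellipsoid
  tof <- .cppTimeOfFlight(det, vox, sosModel@backgroundSOS, !is.null(e),
                          if (is.null(e)) numeric(3) else e$center,
                          if (is.null(e)) rep(1, 3) else e$semiAxes,
                          if (is.null(e)) sosModel@backgroundSOS else e$innerSOS)
  as.numeric(tof)
}
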