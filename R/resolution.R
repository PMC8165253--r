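.fwhmFactor <- 2 * sqrt(2 * log(2))

# Gaussian + constant offset least-squares fit of a 1-D profile.
# Returns FWHM (same units as x), r-squared and the fitted peak position.
.fitGaussianProfile <- function(x, y) {
  ymin <- min(y); ymax <- max(y)
  if (ymax <= ymin) return(list(fwhm = NA_real_, r2 = 0, mu = NA_real_))
  ipk <- which.max(y)
  half <- ymin + (ymax - ymin) / 2
  above <- which(y >= half)
  sigma0 <- max(diff(range(x[above])), diff(x)[1]) / .fwhmFactor
  model <- function(par) par[1] * exp(-(x - par[2])^2 / (2 * par[3]^2)) + par[4]
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A = ymax - ymin, mu = x[ipk], s = sigma0,
                               c0 = ymin),
                       fn = function(par) y - model(par),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance))
    return(list(fwhm = NA_real_, r2 = 0, mu = NA_real_))
  cf <- fit$par
  r2 <- 1 - fit$deviance / sum((y - mean(y))^2)
  list(fwhm = .fwhmFactor * abs(cf[["s"]]), r2 = r2, mu = cf[["mu"]])
}

#' Wire-phantom resolution analysis
#'
#' Estimates axial and lateral resolution from an envelope-detected
#' reconstruction of sub-resolution wires: for each approximate wire
#' position, the intensity peak is located in a local search window, the
#' 1-D axial (z) and lateral (x) profiles through the peak are extracted,
#' and each is fitted with a Gaussian plus constant offset by least squares.
#' The full width at half maximum, `2 sqrt(2 ln 2) sigma` of the fitted
#' Gaussian, is reported as the resolution. Wires whose fit r-squared falls
#' below 0.5 on either axis are flagged unusable and excluded from the
#' lateral-vs-depth trend fit.
#'
#' @param volume an envelope-detected [ReconVolume-class].
#' @param approxPositions n-by-3 matrix (or list of 3-vectors) of
#'   approximate wire centre positions, metres.
#' @param wireAxis axis the wires run along (2 = y, the default); profiles
#'   are taken along z (axial) and the remaining lateral axis.
#' @param searchRadius half-width of the peak search window, metres.
#' @param profileHalfWidth half-length of the extracted profiles, metres.
#' @return A [ResolutionReport-class].
#' @export
estimateResolution <- function(volume, approxPositions, wireAxis = 2L,
                               searchRadius = 0.5e-3,
                               profileHalfWidth = 0.6e-3) {
  stopifnot(is(volume, "ReconVolume"))
  if (!volume@envelopeApplied)
    stop("resolution analysis requires an envelope volume")
  if (wireAxis != 2L) stop("only wires along y (axis 2) are supported")
  if (is.list(approxPositions)) approxPositions <- do.call(rbind, approxPositions)
  approxPositions <- rbind(approxPositions)
  g <- volume@grid
  xs <- gridCoords(g, 1); ys <- gridCoords(g, 2); zs <- gridCoords(g, 3)
  v <- volume@values
  rows <- lapply(seq_len(nrow(approxPositions)), function(w) {
    p0 <- approxPositions[w, ]
    ix <- which(abs(xs - p0[1]) <= searchRadius)
    iy <- which.min(abs(ys - p0[2]))
    iz <- which(abs(zs - p0[3]) <= searchRadius)
    sub <- v[ix, iy, iz, drop = FALSE]
    pk <- arrayInd(which.max(sub), dim(sub))
    ixp <- ix[pk[1]]; izp <- iz[pk[3]]
    selz <- abs(zs - zs[izp]) <= profileHalfWidth
    selx <- abs(xs - xs[ixp]) <= profileHalfWidth
    ax <- .fitGaussianProfile(zs[selz], v[ixp, iy, selz])
    lat <- .fitGaussianProfile(xs[selx], v[selx, iy, izp])
    data.frame(depth = zs[izp], axialFWHM = ax$fwhm, lateralFWHM = lat$fwhm,
               r2Axial = ax$r2, r2Lateral = lat$r2,
               usable = is.finite(ax$fwhm) && is.finite(lat$fwhm) &&
                        ax$r2 >= 0.5 && lat$r2 >= 0.5)
  })
  wires <- do.call(rbind, rows)
  trend <- c(NA_real_, NA_real_)
  ok <- wires$usable
  if (sum(ok) >= 2L) {
    fit <- stats::lm(lateralFWHM ~ depth, data = wires[ok, ])
    trend <- unname(coef(fit))
  }
  new("ResolutionReport", wires = wires, lateralTrend = trend)
}

#' Pulse-duration-limited resolution
#'
#' The elastic-relaxation (stress-confinement) bound on resolution set by
#' the excitation pulse: during a pulse of duration `tau` sound travels
#' `tau * c`, so features closer than that blur together regardless of the
#' detection bandwidth. For the mesoscope's 25 ns pulses in soft tissue this
#' is around 38 um.
#'
#' @param pulseDuration excitation pulse duration, seconds.
#' @param sos speed of sound, m/s.
#' @return Minimum resolvable size in metres.
#' @examples
#' pulseLimitedResolution(25e-9, 1500) * 1e6   # 37.5 um, "around 38"
#' @export
pulseLimitedResolution <- function(pulseDuration, sos) {
  if (pulseDuration <= 0 || sos <= 0)
    stop("pulseDuration and sos must be > 0")
  pulseDuration * sos
}
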