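# Independent numeric oracles used to pin down expected values.

# Wave-equation oracle for the pressure radiated by a uniformly heated
# sphere, via the spherical-means (Poisson) solution
#   p(r, t) = d/dt [ t * M(c t) ],
# where M(rho) is the mean of the initial pressure over the sphere of
# radius rho centred on the detector. For a uniform sphere that mean is the
# spherical-cap area fraction of the shell inside the absorber (elementary
# geometry: a point of the shell at polar angle theta from the source axis
# lies inside iff cos(theta) >= (rho^2 + d^2 - a^2) / (2 rho d)); the wave
# solution is then obtained by numeric central-difference time
# differentiation of t * M(c t), independent of the closed-form N-wave.
sphericalMeansOracle <- function(center, radius, amplitude, detector, times,
                                 sos, dt = 1e-12) {
  d <- sqrt(sum((center - detector)^2))
  sphericalMean <- function(rho) {
    u <- (rho^2 + d^2 - radius^2) / (2 * rho * d)
    amplitude * pmin(pmax((1 - u) / 2, 0), 1)
  }
  tP <- (times + dt) * sphericalMean(sos * (times + dt))
  tM <- (times - dt) * sphericalMean(sos * (times - dt))
  (tP - tM) / (2 * dt)
}

# Numeric line-integral oracle for the two-speed time of flight: midpoint
# sampling of the slowness 1/c along the straight detector -> voxel ray.
tofLineIntegralOracle <- function(detector, voxel, sosModel, n = 2e5) {
  u <- voxel - detector
  L <- sqrt(sum(u^2))
  s <- (seq_len(n) - 0.5) / n
  px <- detector[1] + s * u[1]
  py <- detector[2] + s * u[2]
  pz <- detector[3] + s * u[3]
  e <- sosModel@ellipsoid
  if (is.null(e)) return(L / sosModel@backgroundSOS)
  inside <- ((px - e$center[1]) / e$semiAxes[1])^2 +
            ((py - e$center[2]) / e$semiAxes[2])^2 +
            ((pz - e$center[3]) / e$semiAxes[3])^2 <= 1
  L * mean(ifelse(inside, 1 / e$innerSOS, 1 / sosModel@backgroundSOS))
}

# Brute-force FWHM by half-maximum crossings with linear interpolation,
# independent of any model fit.
fwhmHalfMax <- function(x, y) {
  half <- (max(y) + min(y)) / 2
  ab <- which(y >= half)
  i1 <- min(ab); i2 <- max(ab)
  x1 <- if (i1 > 1) approx(y[(i1 - 1):i1], x[(i1 - 1):i1], xout = half)$y else x[i1]
  x2 <- if (i2 < length(y)) approx(y[i2:(i2 + 1)], x[i2:(i2 + 1)], xout = half)$y else x[i2]
  x2 - x1
}

# Envelope volume holding one (or more) anisotropic Gaussian blobs.
gaussianBlobVolume <- function(grid, centers, sigmas, amplitudes = 1) {
  centers <- rbind(centers); sigmas <- rbind(sigmas)
  amplitudes <- rep_len(amplitudes, nrow(centers))
  xs <- gridCoords(grid, 1); ys <- gridCoords(grid, 2); zs <- gridCoords(grid, 3)
  v <- array(0, dim = grid@shape)
  for (b in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[b, 1])^2 / (2 * sigmas[b, 1]^2))
    gy <- exp(-(ys - centers[b, 2])^2 / (2 * sigmas[b, 2]^2))
    gz <- exp(-(zs - centers[b, 3])^2 / (2 * sigmas[b, 3]^2))
    v <- v + amplitudes[b] * outer(outer(gx, gy), gz)
  }
  new("ReconVolume", grid = grid, values = v, wavelength = NA_real_,
      envelopeApplied = TRUE)
}
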