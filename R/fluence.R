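#' Relative optical fluence by the diffusion approximation
#'
#' Models the depth decay of light in tissue below an arbitrary surface
#' profile: `fluence(x, y, z) = exp(-mu_eff * depthBelowSurface)` with the
#' effective attenuation `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))` of the
#' diffusion approximation, and fluence 1 at and above the surface. A
#' closed-form slab model is used rather than photon-transport Monte Carlo:
#' it is desk-verifiable, and swappable behind the same interface.
#'
#' @param surfaceHeightMap numeric `[nx, ny]` matrix of surface z
#'   coordinates (metres) over the grid columns, or a single number for a
#'   flat surface.
#' @param grid a [ReconGrid-class].
#' @param muA absorption coefficient, 1/m (> 0).
#' @param muSPrime reduced scattering coefficient, 1/m (> 0).
#' @param wavelength nm tag, or `NA`.
#' @return A [FluenceMap-class].
#' @examples
#' g <- makeReconGrid(c(4, 4, 50), 50e-6)
#' f <- computeFluence(0, g, muA = 100, muSPrime = 1000)
#' # mu_eff = sqrt(3 * 100 * 1100) = 574.5 /m; at 2 mm: exp(-1.1489) = 0.317
#' @export
computeFluence <- function(surfaceHeightMap, grid, muA, muSPrime,
                           wavelength = NA_real_) {
  stopifnot(is(grid, "ReconGrid"))
  if (muA <= 0 || muSPrime <= 0)
    stop("optical coefficients must be > 0")
  sh <- grid@shape
  if (length(surfaceHeightMap) == 1L)
    surfaceHeightMap <- matrix(surfaceHeightMap, sh[1], sh[2])
  if (!identical(dim(surfaceHeightMap), as.integer(sh[1:2])))
    stop("surfaceHeightMap must be [nx, ny]")
  muEff <- sqrt(3 * muA * (muA + muSPrime))
  zs <- gridCoords(grid, 3)
  depth <- outer(array(surfaceHeightMap, dim = sh[1:2]), zs,
                 function(s, z) pmax(z - s, 0))
  new("FluenceMap", values = exp(-muEff * depth), grid = grid,
      wavelength = as.numeric(wavelength), muA = muA, muSPrime = muSPrime)
}

#' Fluence compensation
#'
#' Divides a reconstructed volume by the modelled relative fluence, clamped
#' below at `floor` so that deep, dimly illuminated voxels (where the model
#' and the noise both blow up) are amplified by at most `1 / floor`.
#'
#' @param volume a [ReconVolume-class].
#' @param fluence a [FluenceMap-class] on the same grid.
#' @param floor lower clamp on the fluence, fraction in (0, 1).
#' @return A [ReconVolume-class] with compensated values.
#' @export
fluenceCompensate <- function(volume, fluence, floor = 0.05) {
  stopifnot(is(volume, "ReconVolume"), is(fluence, "FluenceMap"))
  if (!(floor > 0 && floor < 1)) stop("floor must lie in (0, 1)")
  if (!identical(volume@grid@shape, fluence@grid@shape) ||
      volume@grid@voxel != fluence@grid@voxel)
    stop("fluence grid does not match the volume grid")
  new("ReconVolume", grid = volume@grid,
      values = volume@values / pmax(fluence@values, floor),
      wavelength = volume@wavelength,
      envelopeApplied = volume@envelopeApplied)
}
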