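#' Depth-coded maximum intensity projection
#'
#' Projects an envelope volume along one axis: each projected pixel carries
#' the maximum intensity along the projection ray and the depth (arg-max
#' index) at which it occurs, with ties broken towards the first
#' (shallowest) index. The depth layer is mapped through a colormap and
#' modulated by the normalised intensity to give the familiar depth-coded
#' vascular rendering.
#'
#' @param volume an envelope-detected [ReconVolume-class].
#' @param axis projection axis (3 = z, the default, for the top view).
#' @param colormap function `n -> n colours`, default
#'   `grDevices::hcl.colors(n, "Spectral")`.
#' @return A list with elements `intensity` (matrix), `depthIndex` (matrix
#'   of 1-based arg-max indices), `depth` (matrix, metres along the
#'   projection axis) and `rgb` (array `[rows, cols, 3]` in `[0, 1]`).
#' @examples
#' ## see the package vignette
#' @export
depthCodedMIP <- function(volume, axis = 3L,
                          colormap = function(n) grDevices::hcl.colors(n, "Spectral")) {
  stopifnot(is(volume, "ReconVolume"))
  if (!volume@envelopeApplied) stop("depth-coded MIP requires an envelope volume")
  v <- volume@values
  intensity <- apply(v, setdiff(1:3, axis), max)
  depthIndex <- apply(v, setdiff(1:3, axis), which.max)
  coords <- gridCoords(volume@grid, axis)
  depth <- matrix(coords[depthIndex], nrow = nrow(depthIndex))
  nd <- dim(v)[axis]
  pal <- grDevices::col2rgb(colormap(nd)) / 255
  scale <- if (max(intensity) > 0) intensity / max(intensity) else intensity
  rgb <- array(0, dim = c(dim(intensity), 3L))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(pal[ch, depthIndex], nrow = nrow(depthIndex)) * scale
  list(intensity = intensity, depthIndex = depthIndex, depth = depth,
       rgb = rgb)
}

#' Dual-wavelength normalised difference
#'
#' Normalises two co-registered envelope volumes by their total energy (the
#' L1 sum of envelope amplitudes, so each normalised volume sums to 1
#' exactly) and forms the voxelwise difference
#' `D = norm(vol1064) - norm(vol800)`. Because 800 nm is isosbestic while
#' oxyhemoglobin dominates the absorption at 1,064 nm, `D` is positive over
#' artery-like voxels and negative over vein-like voxels. Depth projections
#' of the summed image are colour-coded by `D` on a diverging map (positive
#' red, negative blue).
#'
#' @param vol1064,vol800 envelope-detected [ReconVolume-class] objects on
#'   the same grid (excitations at the longer and the isosbestic
#'   wavelength respectively).
#' @param axes projection axes for the colour-coded MIPs.
#' @return A list with `difference` (array), `norm1064`, `norm800`
#'   (normalised arrays) and `mips`, one entry per projection axis with
#'   `intensity`, `difference` (value of D at the projected arg-max voxel)
#'   and `rgb`.
#' @export
dualWavelengthDifference <- function(vol1064, vol800, axes = c(3L, 2L, 1L)) {
  stopifnot(is(vol1064, "ReconVolume"), is(vol800, "ReconVolume"))
  if (!vol1064@envelopeApplied || !vol800@envelopeApplied)
    stop("both volumes must be envelope-detected")
  if (!identical(vol1064@grid@shape, vol800@grid@shape) ||
      vol1064@grid@voxel != vol800@grid@voxel)
    stop("volumes must be co-registered on the same grid")
  e1 <- sum(vol1064@values); e2 <- sum(vol800@values)
  if (e1 <= 0 || e2 <= 0) stop("undefined normalisation: zero total energy")
  nA <- vol1064@values / e1
  nB <- vol800@values / e2
  D <- nA - nB
  tot <- nA + nB
  dmax <- max(abs(D))
  pal <- grDevices::col2rgb(
    grDevices::colorRampPalette(c("blue", "white", "red"))(256L)) / 255
  mips <- lapply(axes, function(ax) {
    keep <- setdiff(1:3, ax)
    intensity <- apply(tot, keep, max)
    amax <- apply(tot, keep, which.max)
    # value of D at each ray's arg-max voxel
    idx <- expand.grid(seq_len(dim(tot)[keep[1]]), seq_len(dim(tot)[keep[2]]))
    full <- matrix(0L, nrow(idx), 3L)
    full[, keep[1]] <- idx[[1]]; full[, keep[2]] <- idx[[2]]
    full[, ax] <- as.vector(amax)
    dval <- matrix(D[full], nrow = dim(tot)[keep[1]])
    ci <- pmin(pmax(round((dval / max(dmax, .Machine$double.eps) + 1) * 127.5) + 1, 1), 256)
    scale <- if (max(intensity) > 0) intensity / max(intensity) else intensity
    rgb <- array(0, dim = c(dim(intensity), 3L))
    for (ch in 1:3)
      rgb[, , ch] <- matrix(pal[ch, ci], nrow = nrow(ci)) * scale
    list(intensity = intensity, difference = dval, rgb = rgb)
  })
  names(mips) <- c("3" = "xy", "2" = "xz", "1" = "yz")[as.character(axes)]
  list(difference = D, norm1064 = nA, norm800 = nB, mips = mips)
}
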