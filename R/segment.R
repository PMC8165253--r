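#' Hysteresis vessel segmentation
#'
#' Segments bright tubular structures from an envelope volume by hysteresis
#' thresholding: voxels at or above `highThresh * max` seed components that
#' grow into all 26-connected voxels at or above `lowThresh * max`;
#' components smaller than `minVoxels` are discarded and the survivors are
#' relabelled by decreasing size (label 1 = largest).
#'
#' @param volume an envelope-detected [ReconVolume-class].
#' @param highThresh,lowThresh seed and growth thresholds as fractions of
#'   the volume maximum, `0 < lowThresh < highThresh <= 1`.
#' @param minVoxels minimum component size in voxels.
#' @return A [VesselSegmentation-class]; empty (with a warning) when no
#'   voxel reaches the seed threshold.
#' @export
segmentVessels <- function(volume, highThresh = 0.5, lowThresh = 0.2,
                           minVoxels = 10L) {
  stopifnot(is(volume, "ReconVolume"))
  if (!volume@envelopeApplied) stop("segmentation requires an envelope volume")
  if (!(lowThresh > 0 && lowThresh < highThresh && highThresh <= 1))
    stop("need 0 < lowThresh < highThresh <= 1")
  vmax <- max(volume@values)
  empty <- function() {
    warning("no voxel above the seed threshold; empty segmentation")
    new("VesselSegmentation",
        labels = array(0L, dim = volume@grid@shape), grid = volume@grid,
        table = data.frame(label = integer(), voxelCount = integer()))
  }
  if (vmax <= 0) return(empty())
  lab <- .cppHysteresisLabel(as.numeric(volume@values), volume@grid@shape,
                             highThresh * vmax, lowThresh * vmax)
  if (max(lab) == 0L) return(empty())
  sizes <- tabulate(lab)
  keep <- which(sizes >= minVoxels)
  if (!length(keep)) {
    lab[] <- 0L
    return(new("VesselSegmentation",
               labels = array(lab, dim = volume@grid@shape),
               grid = volume@grid,
               table = data.frame(label = integer(), voxelCount = integer())))
  }
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(max(lab))
  remap[ord] <- seq_along(ord)
  lab <- ifelse(lab > 0L, remap[lab], 0L)
  new("VesselSegmentation", labels = array(as.integer(lab), dim = volume@grid@shape),
      grid = volume@grid,
      table = data.frame(label = seq_along(ord),
                         voxelCount = sort(sizes[keep], decreasing = TRUE)))
}

#' Per-vessel mean photoacoustic amplitude
#'
#' Arithmetic mean of envelope amplitude over every segmented vessel's
#' voxels, per excitation wavelength. Comparing these means between the
#' isosbestic 800 nm image and the 1,064 nm image (after total-energy
#' normalisation) separates arteries from veins.
#'
#' @param segmentation a [VesselSegmentation-class].
#' @param volumes named list `wavelength -> ReconVolume` on the same grid
#'   as the segmentation.
#' @param normalize if `TRUE` (default), each volume is divided by its
#'   total energy (L1 sum) before averaging, matching the dual-wavelength
#'   comparison.
#' @return data.frame with `label`, `voxelCount` and one `paa<wavelength>`
#'   column per volume.
#' @export
meanPAA <- function(segmentation, volumes, normalize = TRUE) {
  stopifnot(is(segmentation, "VesselSegmentation"))
  if (!length(volumes)) stop("volumes must be a non-empty named list")
  out <- segmentation@table
  if (nrow(out) == 0L) {
    for (wl in names(volumes)) out[[paste0("paa", wl)]] <- numeric(0)
    return(out)
  }
  labs <- as.vector(segmentation@labels)
  sel <- labs > 0L
  for (wl in names(volumes)) {
    vol <- volumes[[wl]]
    stopifnot(is(vol, "ReconVolume"))
    if (!identical(vol@grid@shape, segmentation@grid@shape) ||
        vol@grid@voxel != segmentation@grid@voxel)
      stop("volume grid does not match the segmentation grid")
    v <- as.vector(vol@values)
    if (normalize) {
      tot <- sum(v)
      if (tot <= 0) stop("undefined normalisation: zero total energy")
      v <- v / tot
    }
    m <- tapply(v[sel], labs[sel], mean)
    out[[paste0("paa", wl)]] <- as.numeric(m[as.character(out$label)])
  }
  out
}

#' Overlap of segmentation labels with a ground-truth mask
#'
#' Fraction of each label's voxels lying inside a logical ground-truth
#' mask; used to validate segmentations of simulated phantoms against the
#' generating geometry.
#'
#' @param segmentation a [VesselSegmentation-class].
#' @param mask logical array of the same shape.
#' @return Named numeric vector of overlap fractions, one per label.
#' @export
labelOverlap <- function(segmentation, mask) {
  stopifnot(identical(dim(mask), dim(segmentation@labels)))
  labs <- as.vector(segmentation@labels)
  sel <- labs > 0L
  vapply(split(as.vector(mask)[sel], labs[sel]), mean, numeric(1))
}

#' Voxelise a phantom into a ground-truth mask
#'
#' Marks every grid voxel whose centre lies within `dilate` of any phantom
#' sphere, optionally restricted to labels matching a pattern. Used to
#' build reference masks for validating reconstructions and segmentations.
#'
#' @param phantom an [AbsorberPhantom-class].
#' @param grid a [ReconGrid-class].
#' @param labelPattern regular expression on sphere labels (default all).
#' @param dilate extra radius added around each sphere, metres.
#' @return Logical array of shape `grid@shape`.
#' @export
phantomMask <- function(phantom, grid, labelPattern = ".", dilate = 0) {
  sel <- grepl(labelPattern, phantom@labels)
  mask <- array(FALSE, dim = grid@shape)
  if (!any(sel)) return(mask)
  ctr <- phantom@centers[sel, , drop = FALSE]
  rad <- phantom@radii[sel] + dilate
  xs <- gridCoords(grid, 1); ys <- gridCoords(grid, 2); zs <- gridCoords(grid, 3)
  for (s in seq_len(nrow(ctr))) {
    ix <- which(abs(xs - ctr[s, 1]) <= rad[s])
    iy <- which(abs(ys - ctr[s, 2]) <= rad[s])
    iz <- which(abs(zs - ctr[s, 3]) <= rad[s])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dd <- outer(outer((xs[ix] - ctr[s, 1])^2, (ys[iy] - ctr[s, 2])^2, `+`),
                (zs[iz] - ctr[s, 3])^2, `+`)
    mask[ix, iy, iz] <- mask[ix, iy, iz] | (dd <= rad[s]^2)
  }
  mask
}
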