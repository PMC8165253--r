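.sidecarPath <- function(path) {
  sub("\\.(nii(\\.gz)?|tiff?)$", ".json", path)
}

#' Persist and restore signal sets
#'
#' A [SignalSet-class] is stored as a NIfTI file holding the
#' `[nx, ny, nt]` float32 pressure array plus a JSON sidecar carrying the
#' acquisition metadata (`fs`, `t0`, `pitch`, `origin`, `repRate`,
#' `wavelength`, `seed`). The round trip is lossless at float32 precision;
#' a sidecar missing a required attribute raises a schema error naming it.
#'
#' @param signals a [SignalSet-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `writeSignalSet` returns `path` invisibly; `readSignalSet`
#'   returns a [SignalSet-class].
#' @export
writeSignalSet <- function(signals, path) {
  stopifnot(is(signals, "SignalSet"))
  RNifti::writeNifti(RNifti::asNifti(signals@data, datatype = "float"), path)
  g <- signals@geometry
  meta <- list(container = "PAmeso SignalSet", fs = signals@fs,
               t0 = signals@t0, pitch = g@pitch, origin = g@origin,
               repRate = g@repRate, wavelength = signals@wavelength,
               seed = if (is.na(signals@seed)) NULL else signals@seed)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSignalSet
#' @export
readSignalSet <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  for (field in c("fs", "t0", "pitch", "origin", "repRate", "wavelength"))
    if (is.null(meta[[field]]))
      stop("signal-set schema error: missing attribute '", field, "'")
  g <- makeRasterGeometry(dim(data)[1], dim(data)[2], meta$pitch,
                          meta$repRate, origin = meta$origin)
  new("SignalSet", data = data, fs = meta$fs, t0 = meta$t0, geometry = g,
      wavelength = meta$wavelength,
      seed = if (is.null(meta$seed)) NA else as.integer(meta$seed))
}

#' Persist and restore reconstructed volumes
#'
#' Volumes are written as NIfTI (voxel size carried in `pixdim` and a
#' metre-scaled diagonal affine with the grid origin as translation) or as
#' multipage float TIFF stacks (one page per z slice, values scaled to
#' `[0, 1]` with the scale recorded in the sidecar). Both carry a JSON
#' sidecar with the grid, wavelength and envelope flag; NIfTI round trips
#' are lossless at float32 precision.
#'
#' @param volume a [ReconVolume-class].
#' @param path output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `writeVolume` returns `path` invisibly; `readVolume` returns a
#'   [ReconVolume-class].
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ReconVolume"))
  g <- volume@grid
  vals <- volume@values
  attributes(vals) <- list(dim = dim(vals))
  meta <- list(container = "PAmeso ReconVolume", voxel = g@voxel,
               origin = g@origin, shape = g@shape,
               wavelength = if (is.na(volume@wavelength)) NULL else volume@wavelength,
               envelopeApplied = volume@envelopeApplied)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vals, datatype = "float")
    affine <- diag(c(g@voxel, g@voxel, g@voxel, 1))
    affine[1:3, 4] <- g@origin
    RNifti::sform(img) <- structure(affine, code = 2L)
    img$pixdim <- c(0, rep(g@voxel, 3), 0, 0, 0, 0)
    img$xyzt_units <- 1L    # spatial units: metres
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    vmax <- max(abs(vals), 1e-300)
    slices <- lapply(seq_len(dim(vals)[3]),
                     function(k) (vals[, , k] / vmax + 1) / 2)
    tiff::writeTIFF(slices, path, bits.per.sample = 32L)
    meta$tiffScale <- vmax
  } else stop("unsupported volume format: ", path)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  for (field in c("voxel", "origin", "shape"))
    if (is.null(meta[[field]]))
      stop("volume schema error: missing attribute '", field, "'")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim = dim(img))
  } else if (grepl("\\.tiff?$", path)) {
    slices <- tiff::readTIFF(path, all = TRUE)
    vals <- array(unlist(slices), dim = c(dim(slices[[1]])[1:2], length(slices)))
    vals <- (vals * 2 - 1) * meta$tiffScale
  } else stop("unsupported volume format: ", path)
  grid <- makeReconGrid(meta$shape, meta$voxel, meta$origin)
  new("ReconVolume", grid = grid, values = vals,
      wavelength = if (is.null(meta$wavelength)) NA_real_ else meta$wavelength,
      envelopeApplied = isTRUE(meta$envelopeApplied))
}
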