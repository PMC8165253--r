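# Run expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sphere centres along the segment p0 -> p1 at the given spacing, endpoints
# included.
.sphereChain <- function(p0, p1, spacing) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / spacing) + 1L)
  s <- seq(0, 1, length.out = n)
  cbind(p0[1] + s * (p1[1] - p0[1]),
        p0[2] + s * (p1[2] - p0[2]),
        p0[3] + s * (p1[3] - p0[3]))
}

#' Construct an absorber phantom from parts
#'
#' Low-level constructor used by the wire and vessel phantom generators;
#' also convenient for single-sphere point targets in tests and examples.
#'
#' @param centers n-by-3 matrix of sphere centres, metres.
#' @param radii sphere radii, metres (recycled).
#' @param amplitudes n-by-w matrix of per-wavelength absorbed-energy
#'   amplitudes with wavelength (nm) column names, or a named vector
#'   recycled over spheres.
#' @param labels class tags (recycled).
#' @param so2 oxygen-saturation fractions in `[0, 1]`, `NA` where not
#'   applicable (recycled).
#' @param mediumSOS medium speed of sound, m/s.
#' @param name phantom name.
#' @return An [AbsorberPhantom-class].
#' @examples
#' p <- makeAbsorberPhantom(rbind(c(0, 0, 3e-3)), 50e-6, c("800" = 1))
#' nAbsorbers(p)
#' @export
makeAbsorberPhantom <- function(centers, radii, amplitudes, labels = "absorber",
                                so2 = NA_real_, mediumSOS = 1500,
                                name = "phantom") {
  centers <- rbind(centers)
  n <- nrow(centers)
  if (!is.matrix(amplitudes)) {
    if (is.null(names(amplitudes)))
      stop("amplitudes must be named by wavelength (nm)")
    amplitudes <- matrix(rep(amplitudes, each = n), nrow = n,
                         dimnames = list(NULL, names(amplitudes)))
  }
  new("AbsorberPhantom", centers = unname(centers),
      radii = rep_len(as.numeric(radii), n), amplitudes = amplitudes,
      labels = rep_len(as.character(labels), n),
      so2 = rep_len(as.numeric(so2), n), mediumSOS = mediumSOS, name = name)
}

#' Wire resolution phantom
#'
#' Tungsten-wire resolution targets: thin wires parallel to the y axis at
#' graded depths, each represented as a dense chain of overlapping spheres
#' of radius `wireDiameter / 2` with centre spacing no larger than the
#' radius (so the chain approximates a cylinder to below the noise floor).
#' The bench target uses nine 9 um wires; the wires are much smaller than
#' the system resolution, so their reconstructed profiles are line-spread
#' functions.
#'
#' @param nWires number of wires.
#' @param wireDiameter wire diameter, metres.
#' @param depths depth (z, metres, > 0) of each wire; length `nWires`.
#' @param sos medium speed of sound, m/s.
#' @param xPositions lateral x position of each wire, metres (default all 0,
#'   i.e. centred under the aperture).
#' @param yLength wire length along y, metres (centred at y = 0).
#' @param amplitude absorbed-energy amplitude per sphere.
#' @param wavelength nominal excitation wavelength tag, nm.
#' @return An [AbsorberPhantom-class] with labels `"wire1"`, `"wire2"`, ...
#' @examples
#' makeWirePhantom(3, 9e-6, c(2, 4, 6) * 1e-3, 1500)
#' @export
makeWirePhantom <- function(nWires, wireDiameter, depths, sos = 1500,
                            xPositions = rep(0, nWires), yLength = 2e-3,
                            amplitude = 1, wavelength = 800) {
  if (!length(depths)) stop("depths must be non-empty")
  if (length(depths) != nWires) stop("one depth per wire is required")
  if (any(depths <= 0)) stop("depths must be strictly positive")
  if (wireDiameter <= 0) stop("wireDiameter must be > 0")
  radius <- wireDiameter / 2
  parts <- lapply(seq_len(nWires), function(w) {
    ctr <- .sphereChain(c(xPositions[w], -yLength / 2, depths[w]),
                        c(xPositions[w],  yLength / 2, depths[w]), radius)
    list(centers = ctr, labels = rep(sprintf("wire%d", w), nrow(ctr)))
  })
  centers <- do.call(rbind, lapply(parts, `[[`, "centers"))
  labels <- unlist(lapply(parts, `[[`, "labels"))
  makeAbsorberPhantom(centers, radius,
                      setNames(amplitude, as.character(wavelength)),
                      labels = labels, mediumSOS = sos, name = "wire phantom")
}

#' Random branching vessel phantom with artery/vein labels
#'
#' Generates two random branching trees of sphere-chain vessels -- one
#' arterial, one venous -- below the scan plane. Every sphere's absorbed
#' energy at wavelength lambda is proportional to total hemoglobin times
#' `so2 * eHbO2(lambda) + (1 - so2) * eHb(lambda)`. With the packaged
#' extinction table the 800 nm amplitude is isosbestic (independent of so2
#' at fixed total hemoglobin) while at 1,064 nm the more oxygenated vessel
#' is strictly brighter, which is the contrast the dual-wavelength analysis
#' exploits.
#'
#' @param seed integer RNG seed; identical seeds give identical phantoms.
#' @param nBranches number of branch segments per tree (>= 1).
#' @param so2Artery,so2Vein oxygen saturation of the arterial and venous
#'   tree, fractions in `[0, 1]`.
#' @param extinctionTable data.frame with columns `wavelength`, `eHbO2`,
#'   `eHb`; default [hbExtinctionDefaults()].
#' @param wavelengths wavelengths (nm) to tabulate amplitudes at; all must
#'   be present in `extinctionTable`.
#' @param totalHb total hemoglobin (arbitrary units, common to both trees).
#' @param vesselRadius vessel radius, metres.
#' @param rootDepth depth of the tree roots, metres.
#' @param span lateral extent of the vasculature, metres.
#' @return An [AbsorberPhantom-class]; labels are `"artery<k>"` and
#'   `"vein<k>"` per branch, `so2` filled per sphere.
#' @examples
#' p <- makeVesselPhantom(1, nBranches = 3)
#' table(sub("[0-9]+$", "", p@labels))
#' @export
makeVesselPhantom <- function(seed, nBranches = 4L, so2Artery = 0.95,
                              so2Vein = 0.65,
                              extinctionTable = hbExtinctionDefaults(),
                              wavelengths = c(800, 1064), totalHb = 1,
                              vesselRadius = 80e-6, rootDepth = 1.5e-3,
                              span = 2.4e-3) {
  if (so2Artery < 0 || so2Artery > 1 || so2Vein < 0 || so2Vein > 1)
    stop("so2 must lie in [0, 1]")
  if (!all(c("wavelength", "eHbO2", "eHb") %in% names(extinctionTable)))
    stop("extinctionTable needs columns wavelength, eHbO2, eHb")
  miss <- setdiff(wavelengths, extinctionTable$wavelength)
  if (length(miss))
    stop("extinctionTable is missing wavelength(s): ",
         paste(miss, collapse = ", "))
  if (nBranches < 1L) stop("nBranches must be >= 1")

  idx <- match(wavelengths, extinctionTable$wavelength)
  amp <- function(so2) {
    totalHb * (so2 * extinctionTable$eHbO2[idx] +
               (1 - so2) * extinctionTable$eHb[idx])
  }

  growTree <- function(root, so2, tag) {
    centers <- NULL; labels <- character()
    tips <- list(list(p = root,
                      dir = c(runif(1, -0.3, 0.3), runif(1, 0.7, 1), runif(1, -0.15, 0.15))))
    for (k in seq_len(nBranches)) {
      tip <- tips[[sample.int(length(tips), 1L)]]
      d <- tip$dir + c(runif(1, -0.5, 0.5), runif(1, -0.2, 0.2), runif(1, -0.25, 0.25))
      d <- d / sqrt(sum(d^2))
      len <- runif(1, 0.35, 0.6) * span
      p1 <- tip$p + len * d
      # keep vessels inside the lateral span and below the surface
      p1[1] <- min(max(p1[1], -span / 2), span / 2)
      p1[2] <- min(max(p1[2], -span / 2), span / 2)
      p1[3] <- min(max(p1[3], rootDepth * 0.8), rootDepth + span)
      ctr <- .sphereChain(tip$p, p1, vesselRadius)
      centers <- rbind(centers, ctr)
      labels <- c(labels, rep(sprintf("%s%d", tag, k), nrow(ctr)))
      tips <- c(tips, list(list(p = p1, dir = d)))
    }
    list(centers = centers, labels = labels, so2 = rep(so2, length(labels)))
  }

  .withSeed(seed, {
    art <- growTree(c(-span / 4, -span / 2, rootDepth), so2Artery, "artery")
    ven <- growTree(c( span / 4, -span / 2, rootDepth + 0.2e-3), so2Vein, "vein")
  })
  centers <- rbind(art$centers, ven$centers)
  n <- nrow(centers)
  so2 <- c(art$so2, ven$so2)
  amplitudes <- rbind(matrix(rep(amp(so2Artery), each = nrow(art$centers)),
                             nrow = nrow(art$centers)),
                      matrix(rep(amp(so2Vein), each = nrow(ven$centers)),
                             nrow = nrow(ven$centers)))
  colnames(amplitudes) <- as.character(wavelengths)
  new("AbsorberPhantom", centers = unname(centers),
      radii = rep(vesselRadius, n), amplitudes = amplitudes,
      labels = c(art$labels, ven$labels), so2 = so2, mediumSOS = 1500,
      name = sprintf("vessel phantom (seed %d)", seed))
}
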