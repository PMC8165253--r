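.knownStages <- c("simulate", "characterize", "reconstruct", "analyze")

# Deterministic per-stage substream of the master seed, kept below 2^31 so
# stages can be re-run independently yet reproducibly.
.stageSeed <- function(masterSeed, stageIndex) {
  as.integer((as.numeric(masterSeed) * 1009 + 7919 * stageIndex) %% 2147483647)
}

.cfgGeometry <- function(cfg) {
  nx <- cfg$nx %||% 32L; ny <- cfg$ny %||% 32L
  pitch <- cfg$pitch %||% 100e-6
  origin <- cfg$origin %||%
    if (isTRUE(cfg$center %||% TRUE))
      c(-(nx - 1) * pitch / 2, -(ny - 1) * pitch / 2, 0) else c(0, 0, 0)
  makeRasterGeometry(nx, ny, pitch, cfg$rep_rate %||% 10, origin = origin)
}

.cfgSensor <- function(cfg) {
  makeSensorModel(bw3db = cfg$bw3db %||% 23e6, fs = cfg$fs %||% 125e6,
                  tailAmplitude = cfg$tail_amplitude %||% 0.30,
                  tailDecay = cfg$tail_decay %||% 100e-9,
                  tailFreq = cfg$tail_freq %||% 23e6,
                  nep = cfg$nep %||% 65.8)
}

.cfgPhantom <- function(cfg, seed) {
  type <- cfg$type %||% "wire"
  if (type == "wire") {
    depths <- unlist(cfg$depths %||% c(2e-3, 4e-3, 6e-3))
    makeWirePhantom(length(depths), cfg$wire_diameter %||% 9e-6, depths,
                    sos = cfg$sos %||% 1500,
                    xPositions = unlist(cfg$x_positions %||% rep(0, length(depths))),
                    yLength = cfg$y_length %||% 2e-3,
                    amplitude = cfg$amplitude %||% 5e5)
  } else if (type == "vessel") {
    makeVesselPhantom(seed, nBranches = cfg$n_branches %||% 4L,
                      so2Artery = cfg$so2_artery %||% 0.95,
                      so2Vein = cfg$so2_vein %||% 0.65)
  } else stop("unknown phantom type: ", type)
}

.cfgSOS <- function(cfg) {
  if (is.null(cfg) || is.null(cfg$ellipsoid))
    makeSOSModel((cfg$background %||% 1500))
  else
    makeSOSModel(cfg$background %||% 1500,
                 unlist(cfg$ellipsoid$center),
                 unlist(cfg$ellipsoid$semi_axes),
                 cfg$ellipsoid$inner)
}

.cfgGrid <- function(cfg) {
  makeReconGrid(unlist(cfg$shape %||% c(32L, 32L, 64L)),
                cfg$voxel %||% 50e-6,
                unlist(cfg$origin %||% c(0, 0, 0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate / characterize / reconstruct / analyze pipeline
#'
#' Executes the configured stages in order on a single YAML (or list)
#' configuration, writes every intermediate artifact under the output
#' directory and finishes with a manifest (`manifest.json`) recording the
#' package version, seeds, per-stage timings and the MD5 checksum of every
#' artifact. All randomness derives from the master `seed` through fixed
#' per-stage substreams, so re-running the same configuration reproduces
#' deterministic outputs bit-identically.
#'
#' @param config a list or a path to a YAML file. Recognised top-level
#'   fields: `seed`, `output_dir`, `stages` (subset of
#'   `r paste(PAmeso:::.knownStages, collapse = ", ")`), and the
#'   `geometry`, `sensor`, `phantom`, `simulate`, `sos`, `grid`, `analysis`
#'   sub-configurations (see the vignette for the schema and defaults).
#' @param outputDir overrides `config$output_dir`.
#' @return The manifest, invisibly, as a list.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  stages <- unlist(config$stages %||% c("simulate", "reconstruct", "analyze"))
  bad <- setdiff(stages, .knownStages)
  if (length(bad))
    stop("validation error in field 'stages': unknown stage name '",
         bad[1], "'")
  seed <- as.integer(config$seed %||% 1L)
  outDir <- outputDir %||% config$output_dir %||% stop("output_dir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "PAmeso",
                   version = as.character(packageVersion("PAmeso")),
                   rVersion = as.character(getRversion()),
                   seed = seed, stages = stages,
                   artifacts = list(), timings = list())
  addArtifact <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = basename(path),
                                        md5 = unname(tools::md5sum(path)))
  }
  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     stop("stage '", name, "' failed: ", conditionMessage(e),
                          call. = FALSE)
                   })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    ok
  }

  geometry <- .cfgGeometry(config$geometry %||% list())
  sensor <- .cfgSensor(config$sensor %||% list())
  phantom <- .cfgPhantom(config$phantom %||% list(), .stageSeed(seed, 0L))
  simCfg <- config$simulate %||% list()
  wavelengths <- unlist(simCfg$wavelengths %||% as.numeric(colnames(phantom@amplitudes)))
  signalPaths <- character()
  signalSets <- list()

  if ("simulate" %in% stages) runStage("simulate", function() {
    for (i in seq_along(wavelengths)) {
      wl <- wavelengths[i]
      ss <- simulateSignals(phantom, geometry, sensor,
                            fs = simCfg$fs %||% 125e6,
                            nSamples = simCfg$n_samples %||% 720L,
                            wavelength = wl,
                            noiseSeed = if (isTRUE(simCfg$noise %||% TRUE))
                              .stageSeed(seed, i) else NULL,
                            t0 = simCfg$t0 %||% 0)
      p <- file.path(outDir, sprintf("signals_%g.nii.gz", wl))
      writeSignalSet(ss, p)
      signalPaths[as.character(wl)] <<- p
      signalSets[[as.character(wl)]] <<- ss
      addArtifact(sprintf("signals_%g", wl), p)
    }
  })

  if ("characterize" %in% stages) runStage("characterize", function() {
    fr <- frequencyResponse(sensor@impulseResponse, sensor@fs)
    angles <- seq(-90, 90, by = 1)
    sweep <- lapply(angles, function(a)
      sensor@directivity(a) * sensor@impulseResponse)
    dm <- directivityMap(sweep, angles, sensor@fs)
    noiseSeed <- .stageSeed(seed, 90L)
    nep <- estimateNEP(.withSeed(noiseSeed, rnorm(1e5, sd = sensor@nep)))
    rep <- list(bw3db = bandwidth3dB(fr), coverage = dm@coverage,
                coverageThreshold = dm@threshold, nep = nep)
    p <- file.path(outDir, "sensor_report.json")
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
    addArtifact("sensor_report", p)
  })

  volumes <- list()
  if ("reconstruct" %in% stages) runStage("reconstruct", function() {
    sosModel <- .cfgSOS(config$sos)
    grid <- .cfgGrid(config$grid %||% list())
    for (wl in names(signalSets)) {
      vol <- ubpReconstruct(signalSets[[wl]], sosModel, grid)
      if (isTRUE((config$reconstruct %||% list())$envelope %||% TRUE))
        vol <- hilbertEnvelopeZ(vol)
      p <- file.path(outDir, sprintf("vol_%s.nii.gz", wl))
      writeVolume(vol, p)
      volumes[[wl]] <<- vol
      addArtifact(sprintf("vol_%s", wl), p)
    }
    if (!length(signalSets))
      stop("no signal sets available; run or configure the simulate stage")
  })

  if ("analyze" %in% stages) runStage("analyze", function() {
    acfg <- config$analysis %||% list()
    if (!is.null(acfg$resolution) && length(volumes)) {
      pos <- acfg$resolution$positions
      if (is.null(pos)) {
        wires <- unique(phantom@labels[grepl("^wire", phantom@labels)])
        pos <- t(vapply(wires, function(wlab)
          colMeans(phantom@centers[phantom@labels == wlab, , drop = FALSE]),
          numeric(3)))
      } else pos <- do.call(rbind, lapply(pos, unlist))
      rep <- estimateResolution(volumes[[1]], pos)
      p <- file.path(outDir, "resolution.json")
      jsonlite::write_json(list(wires = rep@wires,
                                lateralTrend = rep@lateralTrend),
                          p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      addArtifact("resolution", p)
    }
    if (isTRUE(acfg$dualwave) && all(c("1064", "800") %in% names(volumes))) {
      seg <- segmentVessels(volumes[["800"]],
                            highThresh = acfg$segment$high %||% 0.5,
                            lowThresh = acfg$segment$low %||% 0.2,
                            minVoxels = acfg$segment$min_voxels %||% 10L)
      paa <- meanPAA(seg, volumes[c("1064", "800")])
      pcsv <- file.path(outDir, "vessel_paa.csv")
      utils::write.csv(paa, pcsv, row.names = FALSE)
      addArtifact("vessel_paa", pcsv)
      dw <- dualWavelengthDifference(volumes[["1064"]], volumes[["800"]])
      p <- file.path(outDir, "dualwave.json")
      jsonlite::write_json(list(nLabels = nrow(paa),
                                totalEnergyNormalization = "L1",
                                maxAbsDifference = max(abs(dw$difference))),
                          p, auto_unbox = TRUE, digits = NA)
      addArtifact("dualwave", p)
    }
  })

  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
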