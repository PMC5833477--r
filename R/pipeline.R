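## Reproducible-run surface: a validated configuration, deterministic
## seeding, metadata-stamped outputs and a JSON-lines stage log. The
## command-line wrapper in inst/scripts/aldhscreen.R is a thin shell over
## runPipeline().

#' Default run configuration
#'
#' Every tunable of the pipeline in one nested list; unknown keys in a
#' user configuration are rejected, and the whole configuration is echoed
#' (with a fingerprint) into every output file header.
#'
#' @return Nested named list: `seed`, `pixel_size`, `gate` (k, min_cells,
#'   control_role), `sphere` (d_min, d_max, sf_min), `normalization`
#'   (neutral_role, full_effect_role, aggregation), `mask`
#'   (mask_fraction), `hits` (threshold), `fast_acting` (t_fast,
#'   t_rebound), `plate` (n_cells_per_well, n_suppressors, n_mimics,
#'   n_toxic), `paths` (cells, platemap, wells, sphere_image, followup).
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    pixel_size = 0.65,
    gate = list(k = 6, min_cells = 200, control_role = "deab"),
    sphere = list(d_min = 50, d_max = 250, sf_min = 0.5),
    normalization = list(neutral_role = "dmso", full_effect_role = "deab",
                         aggregation = "median"),
    mask = list(mask_fraction = 0.5),
    hits = list(threshold = 25),
    fast_acting = list(t_fast = 75, t_rebound = 25),
    plate = list(n_cells_per_well = 5000L, n_suppressors = 10L,
                 n_mimics = 5L, n_toxic = 20L),
    paths = list(cells = NULL, platemap = NULL, wells = NULL,
                 sphere_image = NULL, followup = NULL)
  )
}

#' Load and validate a run configuration
#'
#' Merges a user configuration (a named list or a YAML file path) over
#' [defaultRunConfig()]. Unknown keys at either level are an error --
#' silently ignored options are how screens go wrong.
#'
#' @param config named list, YAML file path, or NULL for the defaults.
#' @return The merged configuration list.
#' @export
loadRunConfig <- function(config = NULL) {
  def <- defaultRunConfig()
  if (is.null(config)) return(def)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      sub <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(sub))
        stop("unknown config key(s) under '", k, "': ",
             paste(sub, collapse = ", "))
      def[[k]][names(config[[k]])] <- config[[k]]
    } else {
      def[[k]] <- config[[k]]
    }
  }
  def
}

screenConfigFrom <- function(cfg) {
  screenConfig(
    neutralRole = cfg$normalization$neutral_role,
    fullEffectRole = cfg$normalization$full_effect_role,
    aggregation = cfg$normalization$aggregation,
    maskFraction = cfg$mask$mask_fraction,
    hitThreshold = cfg$hits$threshold,
    tFast = cfg$fast_acting$t_fast,
    tRebound = cfg$fast_acting$t_rebound
  )
}

pipelineMeta <- function(cfg, extra = character(0)) {
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  c(
    tool = paste0("AldhScreen ",
                  as.character(utils::packageVersion("AldhScreen"))),
    config_hash = configHash(as.character(json)),
    seed = as.character(cfg$seed),
    gate_k = as.character(cfg$gate$k),
    extra
  )
}

logStage <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  line <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run a pipeline stage
#'
#' Commands: `"synth"` generates the reference synthetic screen plate
#' (cells, platemap, ground truth); `"gate"` gates a cell table against
#' its platemap and writes per-well summaries plus the gate parameters;
#' `"screen"` runs the plate-level screen analytics (it fails fast, before
#' any cell data is read, when the platemap lacks the configured control
#' roles); `"spheres"` detects tumorspheres in an image; `"all"` chains
#' synth, gate and screen. All outputs are deterministic given the
#' configured seed and carry the configuration fingerprint in their
#' header; per-stage counts go to a JSON-lines log in `outDir`.
#'
#' @param config configuration for [loadRunConfig()].
#' @param command one of "synth", "gate", "screen", "spheres", "all".
#' @param outDir output directory (created if needed).
#' @return Named list of written file paths plus a `summary` list,
#'   invisibly.
#' @export
runPipeline <- function(config = NULL,
                        command = c("synth", "gate", "screen", "spheres", "all"),
                        outDir = ".") {
  command <- match.arg(command)
  cfg <- loadRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "pipeline.log.jsonl"),
                 open = if (command == "all") "wt" else "at")
  on.exit(close(logCon))
  meta <- pipelineMeta(cfg)
  out <- list()
  summary <- list(seed = cfg$seed)
  logStage(logCon, "start", command = command, seed = cfg$seed,
           config_hash = unname(meta[["config_hash"]]))

  doSynth <- function() {
    sc <- screenScenario(
      seed = cfg$seed, nCellsPerWell = cfg$plate$n_cells_per_well,
      nSuppressors = cfg$plate$n_suppressors, nMimics = cfg$plate$n_mimics,
      nToxic = cfg$plate$n_toxic
    )
    ds <- genPlateDataset(sc$spec)
    cellsPath <- file.path(outDir, "cells.csv")
    pmPath <- file.path(outDir, "platemap.csv")
    truthPath <- file.path(outDir, "truth.csv")
    writeCellTable(ds$cells, cellsPath, meta)
    writePlatemap(ds$platemap, pmPath)
    writeCsvWithMeta(ds$truth, truthPath, meta)
    jsonlite::write_json(sc$truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    logStage(logCon, "synth", wells = nrow(ds$truth), cells = nrow(ds$cells))
    out[["cells"]] <<- cellsPath; out[["platemap"]] <<- pmPath
    out[["truth"]] <<- truthPath
    summary$n_cells <<- nrow(ds$cells)
    list(cells = ds$cells, platemap = ds$platemap)
  }

  doGate <- function(cells = NULL, platemap = NULL) {
    if (is.null(platemap)) {
      if (is.null(cfg$paths$platemap)) stop("paths$platemap is required")
      platemap <- loadPlatemap(cfg$paths$platemap)
    }
    if (is.null(cells)) {
      if (is.null(cfg$paths$cells)) stop("paths$cells is required")
      cells <- readCellTable(cfg$paths$cells)
    }
    sm <- summarizePlate(cells, platemap, k = cfg$gate$k,
                         controlRole = cfg$gate$control_role,
                         minCells = cfg$gate$min_cells)
    gs <- gateStats(sm$gate)
    wellsPath <- file.path(outDir, "wells.csv")
    writeCsvWithMeta(
      sm$wells, wellsPath,
      c(meta, gate_threshold = as.character(gs$threshold),
        gate_mean = as.character(gs$mean), gate_sd = as.character(gs$sd))
    )
    jsonlite::write_json(gs[c("mean", "sd", "k", "threshold", "nControlCells")],
                         file.path(outDir, "gate.json"),
                         auto_unbox = TRUE, digits = NA)
    logStage(logCon, "gate", wells = nrow(sm$wells),
             threshold = gs$threshold)
    out[["wells"]] <<- wellsPath
    summary$gate_threshold <<- gs$threshold
    summary$n_wells <<- nrow(sm$wells)
    sm
  }

  doScreen <- function(wells = NULL, platemap = NULL, gate = NULL) {
    scfg <- screenConfigFrom(cfg)
    if (is.null(platemap) && !is.null(cfg$paths$platemap))
      platemap <- loadPlatemap(cfg$paths$platemap)
    if (!is.null(platemap)) {
      ## fail fast before touching cell data
      for (role in c(scfg$neutralRole, scfg$fullEffectRole)) {
        if (!any(platemap$role == role))
          stop("platemap has no wells with role '", role,
               "' required by the normalization config")
      }
    }
    if (is.null(wells)) {
      if (!is.null(cfg$paths$wells)) {
        wells <- utils::read.csv(cfg$paths$wells, comment.char = "#",
                                 stringsAsFactors = FALSE)
      } else {
        wells <- doGate(platemap = platemap)$wells
      }
    }
    followUp <- NULL
    if (!is.null(cfg$paths$followup))
      followUp <- utils::read.csv(cfg$paths$followup, comment.char = "#",
                                  stringsAsFactors = FALSE)
    res <- screenPlate(wells, scfg, followUp = followUp, gate = gate)
    screenPath <- file.path(outDir, "screen.csv")
    writeCsvWithMeta(screenWells(res), screenPath, meta)
    qc <- plateQC(res)
    qc$signalToBackground <-
      if (is.finite(qc$signalToBackground)) qc$signalToBackground else "Inf"
    jsonlite::write_json(qc, file.path(outDir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
    logStage(logCon, "screen", wells = nrow(screenWells(res)),
             masked = qc$nMasked, hits = qc$nHits, rz_prime = qc$rzPrime)
    out[["screen"]] <<- screenPath
    out[["qc"]] <<- file.path(outDir, "qc.json")
    summary$rz_prime <<- qc$rzPrime
    summary$n_hits <<- qc$nHits
    if (qc$rzPrime <= 0)
      stop("plate QC failure: robust Z' = ", signif(qc$rzPrime, 4))
    res
  }

  if (command == "synth") {
    doSynth()
  } else if (command == "gate") {
    doGate()
  } else if (command == "screen") {
    doScreen()
  } else if (command == "spheres") {
    if (is.null(cfg$paths$sphere_image)) stop("paths$sphere_image is required")
    raw <- tiff::readTIFF(cfg$paths$sphere_image, all = TRUE)[[1]]
    img <- t(raw * 65535)
    sp <- detectSpheres(img, pixelSize = cfg$pixel_size,
                        dMin = cfg$sphere$d_min, dMax = cfg$sphere$d_max,
                        sfMin = cfg$sphere$sf_min)
    spPath <- file.path(outDir, "spheres.csv")
    writeCsvWithMeta(sp, spPath, meta)
    logStage(logCon, "spheres", detected = nrow(sp),
             passing = sum(sp$passes_filters))
    out[["spheres"]] <- spPath
    summary$n_spheres_pass <- sum(sp$passes_filters)
  } else if (command == "all") {
    ds <- doSynth()
    sm <- doGate(cells = ds$cells, platemap = ds$platemap)
    doScreen(wells = sm$wells, platemap = ds$platemap, gate = sm$gate)
  }
  logStage(logCon, "done")
  invisible(c(out, list(summary = summary)))
}
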