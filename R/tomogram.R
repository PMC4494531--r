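#' @include AllClasses.R
NULL

#' Pipeline summary report
#'
#' The per-run analog of the accuracy table: total and valid spot counts,
#' ICP matching RMS, GP cross-validation pooled RMS, and per-stage
#' timings.
#'
#' @slot nTotal,nValid,nLabeled spot counts.
#' @slot icpRMS final registration RMS, mm.
#' @slot gpPooledRMS pooled CV RMS, mm.
#' @slot gpMeanFoldRMS mean of per-fold CV RMS values, mm.
#' @slot timings named per-stage wall times, s.
#' @slot provenance config name/hash and seeds.
#' @export
setClass("PipelineReport",
  representation(nTotal = "integer", nValid = "integer",
                 nLabeled = "integer", icpRMS = "numeric",
                 gpPooledRMS = "numeric", gpMeanFoldRMS = "numeric",
                 timings = "numeric", provenance = "list"))

setMethod("show", "PipelineReport", function(object) {
  cat(sprintf(
    "PipelineReport [%s]: %d/%d valid (%d labeled) | ICP rms %.3f mm | GP pooled rms %.3f mm\n",
    object@provenance$config_name %||% "?", object@nValid, object@nTotal,
    object@nLabeled, object@icpRMS, object@gpPooledRMS))
})

setValidity("PipelineReport", function(object) {
  if (object@nValid > object@nTotal) return("nValid must be <= nTotal")
  if (object@icpRMS < 0 || object@gpPooledRMS < 0) {
    return("rms values must be >= 0")
  }
  TRUE
})

#' Fuse surface geometry with thickness predictions into a 4D tomogram
#'
#' One record per valid spot, order preserved; negative predicted means
#' are clipped to 0 and counted.
#'
#' @param cloud a \linkS4class{SurfacePointCloud}.
#' @param predictions data.frame with columns \code{mean} and
#'   \code{variance} (from \code{\link{gpPredict}}), index-aligned with
#'   the cloud.
#' @param provenance optional provenance list (config hash, seeds,
#'   registration rms).
#' @return a \linkS4class{Tomogram4D}.
#' @export
fuseTomogram <- function(cloud, predictions, provenance = list()) {
  pts <- asPointMatrix(cloud)
  if (nrow(pts) != nrow(predictions)) {
    stop("index mismatch: cloud and predictions must align")
  }
  th <- predictions$mean
  nClip <- sum(th < 0)
  th <- pmax(th, 0)
  new("Tomogram4D", points = pts, thickness = th,
      thicknessVariance = pmax(predictions$variance, 0),
      nClipped = as.integer(nClip), provenance = provenance)
}

#' Run the full synthetic pipeline
#'
#' Executes phantom generation, the laser-grid scan simulation, feature
#' extraction, triangulation, marker pre-alignment plus ICP refinement,
#' thickness label transfer, inverse repeated tenfold GP cross-validation,
#' and tomogram fusion, entirely from one configuration file and one
#' seed. Optionally writes \code{tomogram.ply}, \code{features.csv},
#' \code{cv_records.csv}, \code{transform.json} and \code{report.json}
#' (timings excluded, so reports are byte-reproducible) into
#' \code{outDir}. A stage failure aborts with the stage name; partial
#' artifacts are kept under \code{outDir/failed/}.
#'
#' @param configPath path to a subject YAML configuration.
#' @param seed integer seed overriding the config seed.
#' @param outDir output directory, or NULL to skip artifact writing.
#' @param overrides named list of config overrides (merged recursively),
#'   e.g. \code{list(gp = list(repeats = 1))}.
#' @return a \linkS4class{PipelineReport}; the tomogram, cloud, CV result
#'   and registration are attached as attribute \code{"artifacts"}.
#' @export
runPipeline <- function(configPath, seed = NULL, outDir = NULL,
                        overrides = NULL) {
  cfg <- readSubjectConfig(configPath)
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  if (is.null(seed)) seed <- cfg$seed
  seed <- as.integer(seed)
  timings <- c()
  arts <- new.env()

  failDir <- if (is.null(outDir)) NULL else file.path(outDir, "failed")
  runStage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      if (!is.null(failDir)) {
        dir.create(failDir, recursive = TRUE, showWarnings = FALSE)
        try(writeArtifacts(arts, failDir), silent = TRUE)
      }
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  phantom <- runStage("phantom", generatePhantom(
    thicknessRange = cfg$thickness_range_mm,
    patchSize = cfg$phantom$patch_mm,
    curvatureRadius = cfg$phantom$curvature_radius_mm,
    roughnessAmp = cfg$phantom$roughness_mm,
    seed = seed))
  scanCfg <- configScanConfig(cfg, seed + 1L)
  scan <- runStage("scan", generateNirScan(
    phantom, scanCfg, triNoiseSD = cfg$noise$tri_pixel_sd_px %||% 0,
    seed = seed + 1L))
  mri <- runStage("mri", generateMriDataset(
    phantom, inPlanePitch = cfg$mri$in_plane_pitch_mm,
    outPlanePitch = cfg$mri$out_plane_pitch_mm,
    thicknessNoiseSD = cfg$noise$thickness_sd_mm,
    markerNoiseSD = cfg$noise$marker_sd_mm,
    seed = seed + 2L))
  table <- runStage("features", assembleFeatureTable(scan))
  arts$table <- table
  cloud <- runStage("triangulation", reconstructScan(scan))
  arts$cloud <- cloud

  reg <- runStage("registration", {
    init <- landmarkAlign(phantom@markers, mri@markers)
    icpRefine(cloud, mri, init, new(
      "ICPParams",
      maxIterations = as.integer(cfg$icp$max_iterations),
      rmsChangeTol = cfg$icp$tolerance_mm,
      maxCorrDist = cfg$icp$max_corr_dist_mm,
      trimFraction = cfg$icp$trim_fraction))
  })
  arts$registration <- reg

  labels <- runStage("label_transfer", {
    lab <- transferThicknessLabels(cloud, mri, reg@transform,
                                   radius = cfg$labeling$radius_mm,
                                   registrationRMS = reg@rms,
                                   gate = cfg$labeling$gate_mm)
    full <- rep(NA_real_, nrow(table))
    full[table$valid] <- lab
    table$thickness_mm <- full
    arts$table <- table
    full
  })

  cv <- runStage("gp_cv", {
    fm <- featureMatrix(table)
    inverseCrossValidate(fm$X, fm$y, nFolds = cfg$gp$folds,
                         nRepeats = cfg$gp$repeats, seed = seed + 3L,
                         nRestarts = cfg$gp$restarts %||% 3L)
  })
  arts$cv <- cv

  tomo <- runStage("fuse", {
    fmAll <- featureMatrix(table)
    nTrain <- min(length(fmAll$y), cfg$gp$final_train_size %||% 300L)
    sub <- withSeed(seed + 4L, sample(length(fmAll$y), nTrain))
    final <- gpFit(fmAll$X[sub, , drop = FALSE], fmAll$y[sub],
                   nRestarts = cfg$gp$restarts %||% 3L, seed = seed + 4L)
    fcols <- grep("^f[0-9]+$", names(table), value = TRUE)
    Xv <- cbind(as.matrix(table[table$valid, fcols]),
                table$angle_deg[table$valid])
    pred <- gpPredict(final, unname(Xv))
    fuseTomogram(cloud, pred, provenance = list(
      config_name = cfg$name,
      config_hash = unname(tools::md5sum(configPath)),
      seed = seed, registration_rms_mm = reg@rms))
  })
  arts$tomogram <- tomo

  report <- new("PipelineReport",
                nTotal = nrow(table), nValid = sum(table$valid),
                nLabeled = sum(table$valid & is.finite(table$thickness_mm)),
                icpRMS = reg@rms, gpPooledRMS = cv@pooledRMS,
                gpMeanFoldRMS = cv@meanFoldRMS,
                timings = unlist(timings),
                provenance = tomo@provenance)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeArtifacts(arts, outDir)
    writeReportJSON(report, file.path(outDir, "report.json"))
  }
  attr(report, "artifacts") <- list(phantom = phantom, scan = scan,
                                    mri = mri, table = table,
                                    cloud = cloud, registration = reg,
                                    cv = cv, tomogram = tomo)
  report
}

writeArtifacts <- function(arts, dir) {
  if (!is.null(arts$table)) {
    writeFeatureCSV(arts$table, file.path(dir, "features.csv"))
  }
  if (!is.null(arts$cv)) {
    writeCVRecords(arts$cv, file.path(dir, "cv_records.csv"))
  }
  if (!is.null(arts$registration)) {
    writeTransformJSON(arts$registration@transform,
                       file.path(dir, "transform.json"))
  }
  if (!is.null(arts$tomogram)) {
    writePLY(arts$tomogram, file.path(dir, "tomogram.ply"))
  } else if (!is.null(arts$cloud)) {
    writePLY(arts$cloud, file.path(dir, "cloud.ply"))
  }
  invisible(dir)
}

#' Serialize a pipeline report as JSON
#'
#' Timings are excluded so that reports for a fixed (config, seed) pair
#' are byte-identical across runs.
#'
#' @param report a \linkS4class{PipelineReport}.
#' @param path file path.
#' @export
writeReportJSON <- function(report, path) {
  obj <- list(n_total_spots = report@nTotal, n_valid = report@nValid,
              n_labeled = report@nLabeled,
              icp_rms_mm = report@icpRMS,
              gp_pooled_rms_mm = report@gpPooledRMS,
              gp_mean_fold_rms_mm = report@gpMeanFoldRMS,
              provenance = report@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
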