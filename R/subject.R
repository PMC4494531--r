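#' @include AllClasses.R
NULL

#' Locate and read a shipped subject configuration
#'
#' Three YAML configurations, \code{subject1/2/3}, emulate the three
#' measured regimes (valid-point counts near 888/945/790 of 1024 and noise
#' levels in the reported error ranges). They are stated emulations of
#' those regimes, not claims of equivalence to the original subjects.
#'
#' @param name configuration name, e.g. \code{"subject1"}.
#' @return \code{subjectConfigPath}: the file path;
#'   \code{readSubjectConfig}: the configuration as a nested list.
#' @export
subjectConfigPath <- function(name) {
  p <- system.file("extdata", paste0(name, ".yaml"), package = "nirtomo")
  if (p == "") stop("unknown subject config: ", name)
  p
}

#' @rdname subjectConfigPath
#' @param path path to a YAML configuration file.
#' @export
readSubjectConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("name", "seed", "grid", "thickness_range_mm", "noise",
                "snr_threshold", "imaging", "mri", "phantom", "icp",
                "labeling", "gp")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) {
    stop("config is missing fields: ", paste(miss, collapse = ", "))
  }
  cfg
}

configScanConfig <- function(cfg, seed) {
  pars <- do.call(surrogateParams, cfg$profile$params %||% list())
  scanConfig(gridRows = cfg$grid$rows, gridCols = cfg$grid$cols,
             colSpacing = cfg$grid$col_spacing_mm,
             rowSpacing = cfg$grid$row_spacing_mm,
             spotDiameter = cfg$grid$spot_diameter_mm,
             wavelength = cfg$grid$wavelength_nm,
             rngSeed = seed,
             pixelPitch = cfg$imaging$pixel_pitch_mm,
             imageSize = cfg$imaging$image_size_px,
             noiseCV = cfg$noise$feature_cv,
             backgroundSD = cfg$noise$background_sd_scan %||%
               cfg$noise$background_sd,
             snrThreshold = cfg$snr_threshold_scan %||% cfg$snr_threshold,
             profileModel = cfg$profile$model %||% "surrogate",
             profileParams = pars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the feature-level subject-like dataset
#'
#' Draws one spot per grid point with thickness uniform over the
#' configured range and incidence angle uniform over the configured angle
#' range, evaluates the closed-form annulus features (6 normalized ring
#' means), applies independent multiplicative log-normal noise of the
#' configured CV to each feature, labels each spot with the true thickness
#' plus Gaussian noise, and applies the peak-SNR validity rule, under
#' which roughly the configured fraction of the 1024 spots survives. This
#' is the dataset the GP cross-validation benchmark runs on; the full
#' image pipeline (\code{\link{runPipeline}}) produces the same table from
#' rendered images instead.
#'
#' @param config a configuration list from \code{\link{readSubjectConfig}}.
#' @param seed integer seed (defaults to the config seed).
#' @return a feature table (see \code{\link{assembleFeatureTable}}).
#' @export
makeSubjectDataset <- function(config, seed = config$seed) {
  n <- config$grid$rows * config$grid$cols
  rng <- config$thickness_range_mm
  arng <- config$angle_range_deg %||% c(0, 35)
  pars <- do.call(surrogateParams, config$profile$params %||% list())
  spec <- annulusSpec()
  pitch <- config$imaging$pixel_pitch_mm
  withSeed(as.integer(seed), {
    d <- runif(n, rng[1], rng[2])
    ang <- runif(n, arng[1], arng[2])
    K <- length(spec$radii)
    feat <- matrix(NA_real_, n, K)
    peak <- numeric(n)
    for (i in seq_len(n)) {
      rm <- surrogateRingMeans(d[i], ang[i], spec$radii, pars)
      feat[i, ] <- rm$means / rm$total
      peak[i] <- surrogateAmplitude(d[i], pars) *
        cos(ang[i] * pi / 180) * pitch^2
    }
    sdl <- sqrt(log(1 + config$noise$feature_cv^2))
    feat <- feat * exp(matrix(rnorm(n * K, -sdl^2 / 2, sdl), n, K))
    snr <- peak / max(config$noise$background_sd, 1e-300)
    valid <- snr >= config$snr_threshold
    lab <- d + rnorm(n, 0, config$noise$thickness_sd_mm)
    out <- data.frame(row = rep(seq_len(config$grid$rows),
                                each = config$grid$cols),
                      col = rep(seq_len(config$grid$cols),
                                times = config$grid$rows))
    for (k in seq_len(K)) out[[paste0("f", k)]] <- feat[, k]
    out$angle_deg <- ang
    out$thickness_mm <- lab
    out$valid <- valid
    out$reject_reason <- ifelse(valid, "", "low_snr")
    out
  })
}
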