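#' @include AllClasses.R
NULL

#' Construct a scan configuration
#'
#' Defaults follow the measurement geometry: a 32 x 32 laser grid with
#' 1.5 mm column and 1.0 mm row spacing on the target, a 1.3 mm spot, and
#' 850 nm light (metadata). Imaging and noise defaults are the shipped
#' subject-like regime.
#'
#' @param gridRows,gridCols grid dimensions.
#' @param colSpacing,rowSpacing target-plane spacings, mm.
#' @param spotDiameter laser spot diameter, mm.
#' @param wavelength nm, metadata.
#' @param photonsPerSpot photons per Monte-Carlo profile knot.
#' @param rngSeed integer seed recorded in outputs.
#' @param pixelPitch HDR pixel pitch, mm/px.
#' @param imageSize HDR image side, px.
#' @param noiseCV multiplicative pixel noise CV.
#' @param backgroundSD additive background noise SD, image units.
#' @param snrThreshold validity threshold on peak-over-background SNR.
#' @param profileModel "surrogate" or "mc".
#' @param profileKnots thickness knots for the "mc" profile library, mm.
#' @param profileParams surrogate family parameters
#'   (\code{\link{surrogateParams}}).
#' @return a \linkS4class{ScanConfig}.
#' @export
scanConfig <- function(gridRows = 32L, gridCols = 32L, colSpacing = 1.5,
                       rowSpacing = 1.0, spotDiameter = 1.3,
                       wavelength = 850, photonsPerSpot = 20000L,
                       rngSeed = 1L, pixelPitch = 0.1, imageSize = 141L,
                       noiseCV = 0.05, backgroundSD = 5.4e-4,
                       snrThreshold = 5, profileModel = "surrogate",
                       profileKnots = c(0.5, 1, 2, 3, 4, 6, 8, 10, 12, 14,
                                        16, 18, 20),
                       profileParams = surrogateParams()) {
  new("ScanConfig", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), colSpacing = colSpacing,
      rowSpacing = rowSpacing, spotDiameter = spotDiameter,
      wavelength = wavelength, photonsPerSpot = as.integer(photonsPerSpot),
      rngSeed = as.integer(rngSeed), pixelPitch = pixelPitch,
      imageSize = as.integer(imageSize), noiseCV = noiseCV,
      backgroundSD = backgroundSD, snrThreshold = snrThreshold,
      profileModel = profileModel, profileKnots = profileKnots,
      profileParams = profileParams)
}

#' Simulated grid scan
#'
#' Container for one simulated laser-grid acquisition: the per-spot HDR
#' images, a per-spot metadata table (grid index, ground-truth surface
#' point, thickness and incidence angle, triangulation pixel, SNR and
#' validity), and the configuration and geometry it was generated from.
#'
#' @slot images list of HDR image matrices, one per grid point.
#' @slot meta per-spot data.frame (see \code{\link{generateNirScan}}).
#' @slot config the \linkS4class{ScanConfig}.
#' @slot camera the triangulation \linkS4class{CameraModel}.
#' @slot galvo the \linkS4class{GalvoCalibration}.
#' @slot seed integer seed of the acquisition.
#' @export
setClass("NIRScan",
  representation(images = "list", meta = "data.frame",
                 config = "ScanConfig", camera = "CameraModel",
                 galvo = "GalvoCalibration", seed = "integer"))

setMethod("show", "NIRScan", function(object) {
  cat(sprintf("NIRScan: %d spots (%d valid), %s profile model, seed %d\n",
              nrow(object@meta), sum(object@meta$valid),
              object@config@profileModel, object@seed))
})

# per-spot radial profile factory for the configured model
profileFactory <- function(phantom, config) {
  if (config@profileModel == "surrogate") {
    pars <- config@profileParams
    function(thickness, angle) surrogateProfile(thickness, angle, pars)
  } else {
    knots <- sort(config@profileKnots)
    dens <- lapply(knots, function(d) {
      profileDensity(simulateBackscatter(
        phantom@tissueProps, phantom@boneProps, thickness = d,
        beamRadius = config@spotDiameter / 2,
        nPhotons = config@photonsPerSpot))
    })
    function(thickness, angle) {
      d <- min(max(thickness, knots[1]), knots[length(knots)])
      i <- findInterval(d, knots, rightmost.closed = TRUE)
      i <- min(i, length(knots) - 1L)
      w <- (d - knots[i]) / (knots[i + 1] - knots[i])
      fi <- dens[[i]]; fj <- dens[[i + 1]]
      function(r) (1 - w) * fi(r) + w * fj(r)
    }
  }
}

#' Simulate a full laser-grid NIR acquisition
#'
#' For every grid index: casts the galvo ray, intersects it with the
#' phantom surface, evaluates the local thickness and incidence angle,
#' generates the backscatter profile (closed-form surrogate, or a
#' Monte-Carlo profile library interpolated across thickness), renders the
#' HDR spot image with the configured noise, projects the true surface
#' point into the triangulation camera (plus pixel-localization noise),
#' and applies the SNR validity rule. Rays that miss the patch are marked
#' invalid, not errors. Deterministic for a fixed seed.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param config a \linkS4class{ScanConfig}.
#' @param camera triangulation \linkS4class{CameraModel}.
#' @param galvo \linkS4class{GalvoCalibration}; derived from \code{config}
#'   when \code{NULL}.
#' @param triNoiseSD pixel-localization noise SD in the triangulation
#'   camera, px.
#' @param seed integer seed (defaults to \code{config@rngSeed}).
#' @return a \linkS4class{NIRScan}. The \code{meta} slot has columns
#'   \code{row, col, hit, x, y, z, thickness, angle_deg, tri_px, tri_py,
#'   snr, valid}.
#' @export
generateNirScan <- function(phantom, config,
                            camera = defaultTriangulationCamera(),
                            galvo = NULL, triNoiseSD = 0,
                            seed = config@rngSeed) {
  if (is.null(galvo)) {
    galvo <- galvoCalibrationForGrid(config@gridRows, config@gridCols,
                                     config@colSpacing, config@rowSpacing)
  }
  nr <- config@gridRows; nc <- config@gridCols
  n <- nr * nc
  withSeed(as.integer(seed), {
    makeProfile <- profileFactory(phantom, config)
    meta <- data.frame(row = rep(seq_len(nr), each = nc),
                       col = rep(seq_len(nc), times = nr),
                       hit = FALSE, x = NA_real_, y = NA_real_,
                       z = NA_real_, thickness = NA_real_,
                       angle_deg = NA_real_, tri_px = NA_real_,
                       tri_py = NA_real_, snr = NA_real_, valid = FALSE)
    images <- vector("list", n)
    half <- phantom@patchSize / 2
    for (i in seq_len(n)) {
      ray <- galvoRay(galvo, meta$row[i], meta$col[i])
      froot <- function(t) {
        p <- ray$origin + t * ray$direction
        p[3] - surfaceHeight(phantom, p[1], p[2])
      }
      tHit <- tryCatch(
        uniroot(froot, c(0.5 * galvo@pivot[3], 1.5 * galvo@pivot[3]),
                tol = 1e-10)$root,
        error = function(e) NA_real_)
      if (is.na(tHit)) next
      p <- ray$origin + tHit * ray$direction
      if (abs(p[1]) > half[1] || abs(p[2]) > half[2]) next
      meta$hit[i] <- TRUE
      meta$x[i] <- p[1]; meta$y[i] <- p[2]; meta$z[i] <- p[3]
      meta$thickness[i] <- thicknessAt(phantom, p[1], p[2])
      nrm <- as.numeric(surfaceNormalAt(phantom, p[1], p[2]))
      meta$angle_deg[i] <- computeIncidentAngle(nrm, ray$direction)
      prof <- makeProfile(meta$thickness[i], meta$angle_deg[i])
      images[[i]] <- renderSpotImage(prof, meta$angle_deg[i],
                                     config@pixelPitch, config@imageSize,
                                     config@noiseCV, config@backgroundSD)
      px <- projectPoint(camera, p)
      meta$tri_px[i] <- px[1] + rnorm(1, 0, triNoiseSD)
      meta$tri_py[i] <- px[2] + rnorm(1, 0, triNoiseSD)
      meta$snr[i] <- spotSNR(images[[i]])
      meta$valid[i] <- meta$snr[i] >= config@snrThreshold
    }
    new("NIRScan", images = images, meta = meta, config = config,
        camera = camera, galvo = galvo, seed = as.integer(seed))
  })
}
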