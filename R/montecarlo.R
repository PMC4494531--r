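#' @include AllClasses.R
NULL

# run expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate NIR backscatter from layered tissue
#'
#' Weight-tracking Monte-Carlo photon transport in a two-layer slab: soft
#' tissue of the given thickness over semi-infinite bone. Photons are
#' launched over a top-hat beam disc, propagate with exponential free paths
#' under the total attenuation of the current layer, deposit the absorbed
#' weight fraction at each interaction, scatter by the Henyey-Greenstein
#' phase function, and exit (and are scored) as soon as they cross the top
#' surface; the boundary is matched-index, so no Fresnel reflection or
#' refraction is applied. Low-weight photons undergo Russian roulette.
#'
#' The returned profile is the exit weight per radial bin (distance of the
#' exit point from the beam axis) divided by the number of launched
#' photons. The weight ledger (launched = exited + absorbed + killed +
#' lost) is conserved to 1e-6 relative on every run; \code{lost} counts
#' weight transmitted beyond \code{zCutoff} or exceeding the step cap.
#'
#' @param tissue \linkS4class{OpticalProperties} of the soft-tissue layer.
#' @param bone \linkS4class{OpticalProperties} of the bone half-space;
#'   \code{NULL} makes the medium semi-infinite tissue.
#' @param thickness soft-tissue thickness, mm (0 = bare bone; \code{Inf} =
#'   semi-infinite tissue).
#' @param beamRadius top-hat beam radius, mm (default 0.65, the 1.3 mm
#'   laser spot).
#' @param incidenceAngle beam incidence angle from the surface normal,
#'   degrees.
#' @param nPhotons photons to launch.
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @param binWidth,maxRadius radial binning of the exit profile, mm
#'   (defaults 0.1 and 10; the last bin collects overflow).
#' @param rouletteThreshold,rouletteSurvival Russian-roulette weight
#'   threshold and survival probability (defaults 1e-4 and 0.1).
#' @param zCutoff depth at which photons are counted as transmitted, mm.
#' @param maxSteps per-photon interaction cap (safety).
#' @param depthBinWidth,depthMax binning of the exit-weighted maximum-depth
#'   histogram, mm.
#' @return a \linkS4class{BackscatterProfile}.
#' @export
simulateBackscatter <- function(tissue, bone = NULL, thickness,
                                beamRadius = 0.65, incidenceAngle = 0,
                                nPhotons, seed = NULL, binWidth = 0.1,
                                maxRadius = 10, rouletteThreshold = 1e-4,
                                rouletteSurvival = 0.1, zCutoff = 400,
                                maxSteps = 200000L, depthBinWidth = 0.25,
                                depthMax = 60) {
  stopifnot(is(tissue, "OpticalProperties"))
  if (nPhotons < 1) stop("nPhotons must be >= 1")
  if (is.na(thickness) || thickness < 0) stop("thickness must be >= 0")
  if (is.null(bone)) bone <- tissue
  stopifnot(is(bone, "OpticalProperties"))
  if (!is.finite(thickness)) {
    bone <- tissue
    thickness <- 0
  }
  res <- withSeed(seed,
    mc_backscatter_cpp(tissue@mua, tissue@mus, tissue@g,
                       bone@mua, bone@mus, bone@g,
                       thickness, beamRadius, incidenceAngle,
                       as.integer(nPhotons), binWidth, maxRadius,
                       rouletteThreshold, rouletteSurvival,
                       zCutoff, as.integer(maxSteps),
                       depthBinWidth, depthMax))
  nb <- length(res$radial)
  ledger <- c(launched = as.numeric(nPhotons), exited = res$exited,
              absorbed = res$absorbed, killed = res$killed,
              lost = res$lost)
  new("BackscatterProfile",
      binEdges = c(seq(0, by = binWidth, length.out = nb), Inf),
      weights = res$radial / nPhotons,
      ledger = ledger,
      depthEdges = c(seq(0, by = depthBinWidth,
                         length.out = length(res$depth_hist)), Inf),
      depthHist = res$depth_hist,
      maxDepthExit = res$max_depth_exit,
      nPhotons = as.numeric(nPhotons),
      nExited = res$n_exited)
}

#' Total diffuse reflectance of a profile
#'
#' Exiting weight per launched photon.
#'
#' @param profile a \linkS4class{BackscatterProfile}.
#' @return scalar in [0, 1].
#' @export
totalReflectance <- function(profile) {
  unname(profile@ledger["exited"] / profile@ledger["launched"])
}

#' Piecewise-constant radial intensity density of a profile
#'
#' Converts the binned exit weights into a surface intensity density
#' (weight per mm^2) as a function of radius, for spot-image rendering.
#' The overflow bin is dropped.
#'
#' @param profile a \linkS4class{BackscatterProfile}.
#' @return a function \code{f(r)} returning intensity per mm^2.
#' @export
profileDensity <- function(profile) {
  edges <- profile@binEdges
  nb <- length(profile@weights) - 1L      # drop overflow
  lo <- edges[seq_len(nb)]
  hi <- edges[seq_len(nb) + 1L]
  dens <- profile@weights[seq_len(nb)] / (pi * (hi^2 - lo^2))
  rmax <- hi[nb]
  function(r) {
    idx <- pmin(pmax(floor(r / (hi[1] - lo[1])) + 1, 1), nb)
    out <- dens[idx]
    out[r >= rmax] <- 0
    out
  }
}
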