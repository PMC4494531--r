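#' @include AllClasses.R
NULL

# band-limited cosine random field: sum_k a_k cos(2*pi*(u_k x + v_k y) + phi_k)
# frequencies are drawn with wavelengths in [minWavelength, maxWavelength]
makeCosField <- function(nModes, amplitude, minWavelength = 15,
                         maxWavelength = 40) {
  wl <- runif(nModes, minWavelength, maxWavelength)
  th <- runif(nModes, 0, 2 * pi)
  a <- rnorm(nModes)
  a <- a / sqrt(sum(a^2)) * amplitude * sqrt(2)
  list(a = a, u = cos(th) / wl, v = sin(th) / wl,
       phi = runif(nModes, 0, 2 * pi))
}

evalCosField <- function(field, x, y) {
  out <- numeric(length(x))
  for (k in seq_along(field$a)) {
    out <- out + field$a[k] *
      cos(2 * pi * (field$u[k] * x + field$v[k] * y) + field$phi[k])
  }
  out
}

evalCosFieldGrad <- function(field, x, y) {
  gx <- numeric(length(x))
  gy <- numeric(length(x))
  for (k in seq_along(field$a)) {
    s <- field$a[k] * 2 * pi *
      sin(2 * pi * (field$u[k] * x + field$v[k] * y) + field$phi[k])
    gx <- gx - s * field$u[k]
    gy <- gy - s * field$v[k]
  }
  cbind(gx, gy)
}

#' Generate a synthetic forehead-like phantom
#'
#' Builds the ground-truth object the pipeline is evaluated against: a
#' smooth dome-shaped surface patch with band-limited random relief, an
#' independent smooth soft-tissue thickness field affinely calibrated to
#' the requested range (and clamped to it), fiducial markers rigidly
#' attached near the patch corners, and a random ground-truth rigid
#' transform into the MRI frame (rotation at most \code{maxMriRotation}
#' degrees, translation at most \code{maxMriTranslation} mm per axis).
#' Deterministic for a fixed seed.
#'
#' @param thicknessRange clamp range of the thickness field, mm; must lie
#'   within [0.5, 20] (a degenerate range \code{c(d, d)} yields a constant
#'   field).
#' @param patchSize rectangular patch extent, mm (x, y), centred on the
#'   origin.
#' @param curvatureRadius dome radius of curvature, mm (default 80,
#'   forehead-like).
#' @param roughnessAmp SD of the surface relief field, mm.
#' @param thicknessRoughness relative amplitude of the thickness field
#'   before range calibration (shape only; the range is set by
#'   \code{thicknessRange}).
#' @param nModes cosine modes per random field.
#' @param nMarkers number of fiducial markers (>= 3).
#' @param markerNoiseSD isotropic perturbation of the stored marker
#'   centroids, mm.
#' @param tissue,bone layer \linkS4class{OpticalProperties}.
#' @param maxMriRotation,maxMriTranslation bounds of the random
#'   ground-truth MRI offset (degrees, mm).
#' @param seed integer seed (required).
#' @return a \linkS4class{Phantom}.
#' @export
generatePhantom <- function(thicknessRange = c(2, 14),
                            patchSize = c(48, 32),
                            curvatureRadius = 80,
                            roughnessAmp = 0.3,
                            thicknessRoughness = 1,
                            nModes = 8L,
                            nMarkers = 4L,
                            markerNoiseSD = 0,
                            tissue = defaultTissueProperties(),
                            bone = defaultBoneProperties(),
                            maxMriRotation = 20,
                            maxMriTranslation = 50,
                            seed) {
  if (missing(seed)) stop("a seed is required")
  if (length(thicknessRange) != 2L || any(!is.finite(thicknessRange)) ||
      thicknessRange[1] < 0 || thicknessRange[1] > thicknessRange[2]) {
    stop("invalid thickness range: need 0 <= min <= max")
  }
  if (thicknessRange[1] < 0.5 || thicknessRange[2] > 20) {
    stop("thickness range must lie within [0.5, 20] mm")
  }
  withSeed(as.integer(seed), {
    surfField <- makeCosField(nModes, roughnessAmp)
    thickField <- makeCosField(nModes, thicknessRoughness)
    # calibrate the thickness field to the requested range on a dense grid
    gx <- seq(-patchSize[1] / 2, patchSize[1] / 2, length.out = 201)
    gy <- seq(-patchSize[2] / 2, patchSize[2] / 2, length.out = 201)
    gg <- expand.grid(x = gx, y = gy)
    raw <- evalCosField(thickField, gg$x, gg$y)
    thickField$rawMin <- min(raw)
    thickField$rawMax <- max(raw)
    thickField$range <- thicknessRange
    surface <- list(curvatureRadius = curvatureRadius, field = surfField)
    # markers near the patch corners, standing proud of the surface
    mx <- 0.55 * patchSize[1] / 2 * c(-1, 1, 1, -1, 0, 0)[seq_len(nMarkers)]
    my <- 0.55 * patchSize[2] / 2 * c(-1, -1, 1, 1, -1, 1)[seq_len(nMarkers)]
    mz <- -(mx^2 + my^2) / (2 * curvatureRadius) +
      evalCosField(surfField, mx, my) + 12
    markers <- data.frame(label = paste0("M", seq_len(nMarkers)),
                          x = mx + rnorm(nMarkers, 0, markerNoiseSD),
                          y = my + rnorm(nMarkers, 0, markerNoiseSD),
                          z = mz + rnorm(nMarkers, 0, markerNoiseSD),
                          stringsAsFactors = FALSE)
    mriT <- randomRigidTransform(maxMriRotation, maxMriTranslation)
    new("Phantom", patchSize = as.numeric(patchSize), surface = surface,
        thicknessField = thickField,
        thicknessRange = as.numeric(thicknessRange),
        tissueProps = tissue, boneProps = bone, markers = markers,
        mriTransform = mriT, seed = as.integer(seed))
  })
}

#' Evaluate the phantom surface and thickness fields
#'
#' \code{surfaceHeight} returns the height \eqn{z(x, y)} in mm;
#' \code{surfaceNormalAt} the unit normal (oriented toward the scanner,
#' +z); \code{thicknessAt} the soft-tissue thickness in mm.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param x,y coordinates, mm (vectorized).
#' @return numeric vector (height, thickness) or n x 3 matrix (normals).
#' @export
surfaceHeight <- function(phantom, x, y) {
  s <- phantom@surface
  -(x^2 + y^2) / (2 * s$curvatureRadius) + evalCosField(s$field, x, y)
}

#' @rdname surfaceHeight
#' @export
surfaceNormalAt <- function(phantom, x, y) {
  s <- phantom@surface
  g <- evalCosFieldGrad(s$field, x, y)
  gx <- -x / s$curvatureRadius + g[, 1]
  gy <- -y / s$curvatureRadius + g[, 2]
  n <- cbind(-gx, -gy, 1)
  n / sqrt(rowSums(n^2))
}

#' @rdname surfaceHeight
#' @export
thicknessAt <- function(phantom, x, y) {
  f <- phantom@thicknessField
  rng <- f$range
  if (diff(rng) == 0 || f$rawMax - f$rawMin < .Machine$double.eps) {
    return(rep(rng[1], length(x)))
  }
  raw <- evalCosField(f, x, y)
  d <- rng[1] + diff(rng) * (raw - f$rawMin) / (f$rawMax - f$rawMin)
  pmin(pmax(d, rng[1]), rng[2])
}
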