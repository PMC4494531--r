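#' @include AllClasses.R
NULL

#' Generate the MRI-like ground-truth thickness map
#'
#' Samples the phantom surface on an anisotropic grid — the in-plane pitch
#' along x (default 0.15 mm) and the out-of-plane (slice) pitch along y
#' (default 1 mm) — evaluates the true soft-tissue thickness at each
#' sample, adds Gaussian segmentation noise, and maps points and marker
#' centroids through the phantom's ground-truth NIR-to-MRI transform with
#' marker localization noise. Deterministic for a fixed seed.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param inPlanePitch in-plane sampling pitch, mm (> 0).
#' @param outPlanePitch slice spacing, mm (> 0).
#' @param thicknessNoiseSD segmentation noise SD on thickness, mm.
#' @param markerNoiseSD marker localization noise SD, mm.
#' @param seed integer seed.
#' @return an \linkS4class{MRIThicknessMap}.
#' @export
generateMriDataset <- function(phantom, inPlanePitch = 0.15,
                               outPlanePitch = 1.0, thicknessNoiseSD = 0,
                               markerNoiseSD = 0, seed = 1L) {
  if (inPlanePitch <= 0 || outPlanePitch <= 0) stop("pitches must be > 0")
  half <- phantom@patchSize / 2
  xs <- seq(-half[1], half[1], by = inPlanePitch)
  ys <- seq(-half[2], half[2], by = outPlanePitch)
  g <- expand.grid(x = xs, y = ys)
  z <- surfaceHeight(phantom, g$x, g$y)
  pts <- cbind(g$x, g$y, z)
  th <- thicknessAt(phantom, g$x, g$y)
  withSeed(as.integer(seed), {
    th <- th + rnorm(length(th), 0, thicknessNoiseSD)
    pts <- applyTransform(phantom@mriTransform, pts)
    mk <- phantom@markers
    mp <- applyTransform(phantom@mriTransform,
                         as.matrix(mk[, c("x", "y", "z")]))
    mp <- mp + matrix(rnorm(length(mp), 0, markerNoiseSD), nrow(mp), 3)
    markers <- data.frame(label = mk$label, x = mp[, 1], y = mp[, 2],
                          z = mp[, 3], stringsAsFactors = FALSE)
    new("MRIThicknessMap", points = unname(pts), thickness = th,
        markers = markers)
  })
}
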