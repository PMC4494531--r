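#' @include AllClasses.R
NULL

#' Render an HDR spot image from a radial profile
#'
#' Resamples a rotationally symmetric backscatter profile onto the pixel
#' grid of the co-axial (inBeam) HDR camera. Oblique incidence
#' foreshortens the spot into an ellipse (the surface-plane radius is
#' recovered as \eqn{\sqrt{u^2 + (v/\cos\theta)^2}} with the tilt axis
#' along the image rows) and darkens the image by the cosine law. Optional
#' per-pixel multiplicative log-normal noise (unit mean) and additive
#' Gaussian background noise are applied last; pixel values are clamped at
#' 0 so intensities stay non-negative.
#'
#' @param profile either a function \code{f(r)} giving surface intensity
#'   per mm^2, or a \linkS4class{BackscatterProfile} (converted via
#'   \code{\link{profileDensity}}).
#' @param incidenceAngle incidence angle, degrees in [0, 90).
#' @param pixelPitch mm per pixel (> 0).
#' @param imageSize image side length, px (square image).
#' @param noiseCV coefficient of variation of the multiplicative noise;
#'   0 disables.
#' @param backgroundSD additive background noise SD; 0 disables.
#' @param seed optional integer seed for the noise draws.
#' @return an \code{imageSize} x \code{imageSize} matrix; pixel (1,1) is
#'   the top-left pixel, the spot center lies at the image center. The
#'   pixel pitch is attached as attribute \code{"pixelPitch"}.
#' @export
renderSpotImage <- function(profile, incidenceAngle = 0, pixelPitch = 0.1,
                            imageSize = 141L, noiseCV = 0,
                            backgroundSD = 0, seed = NULL) {
  stopifnot(pixelPitch > 0, imageSize >= 1)
  if (incidenceAngle < 0 || incidenceAngle >= 90) {
    stop("incidence angle must lie in [0, 90)")
  }
  f <- if (is(profile, "BackscatterProfile")) profileDensity(profile)
       else profile
  n <- as.integer(imageSize)
  ct <- cos(incidenceAngle * pi / 180)
  cc <- (seq_len(n) - 1 - (n - 1) / 2) * pixelPitch
  u <- matrix(cc, n, n, byrow = TRUE)   # along rows (columns vary)
  v <- matrix(cc, n, n)                 # along columns (rows vary)
  r <- sqrt(u^2 + (v / ct)^2)
  img <- f(r) * ct * pixelPitch^2
  dim(img) <- c(n, n)
  withSeed(seed, {
    if (noiseCV > 0) {
      sdl <- sqrt(log(1 + noiseCV^2))
      img <- img * exp(matrix(rnorm(n * n, -sdl^2 / 2, sdl), n, n))
    }
    if (backgroundSD > 0) {
      img <- pmax(img + matrix(rnorm(n * n, 0, backgroundSD), n, n), 0)
    }
    img
  })
  attr(img, "pixelPitch") <- pixelPitch
  img
}
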