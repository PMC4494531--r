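#' @include AllClasses.R
NULL

#' Parameters of the closed-form backscatter profile family
#'
#' The pipeline's fast stand-in for per-spot photon transport: a
#' single-exponential radial intensity density
#' \deqn{I(r; d, \theta) = A_0 e^{-\kappa d} \exp(-\mu(d, \theta)\, r)}
#' with effective radial attenuation
#' \deqn{\mu(d, \theta) = \max(a - b\, d,\; \mu_{min}) \cdot
#'       (1 - c\,(1 - \cos\theta)).}
#' Thicker soft tissue lets light diffuse deeper before re-emerging, so the
#' halo broadens (\eqn{\mu} falls with \eqn{d}) while the total return
#' darkens (\eqn{e^{-\kappa d}}, bone being the brighter medium) — the
#' qualitative behaviour of the Monte-Carlo model. Oblique incidence
#' stretches the entry spot along the surface and mimics extra broadening
#' (the \eqn{c} term), which is what makes the incident angle a genuine
#' confounder of the thickness features.
#'
#' @param a zero-thickness radial attenuation, 1/mm.
#' @param b attenuation decrease per mm of soft tissue, 1/mm^2.
#' @param muMin attenuation floor, 1/mm.
#' @param angleBroadening dimensionless angle-coupling coefficient c.
#' @param amplitudeDecay amplitude decay \eqn{\kappa} per mm thickness.
#' @param A0 amplitude at zero thickness, intensity per mm^2.
#' @return a named list.
#' @export
surrogateParams <- function(a = 1.1, b = 0.06, muMin = 0.2,
                            angleBroadening = 0.5, amplitudeDecay = 0.2,
                            A0 = 1.0) {
  list(a = a, b = b, muMin = muMin, angleBroadening = angleBroadening,
       amplitudeDecay = amplitudeDecay, A0 = A0)
}

surrogateMu <- function(thickness, incidenceAngle, pars) {
  ct <- cos(incidenceAngle * pi / 180)
  pmax(pars$a - pars$b * thickness, pars$muMin) *
    (1 - pars$angleBroadening * (1 - ct))
}

surrogateAmplitude <- function(thickness, pars) {
  pars$A0 * exp(-pars$amplitudeDecay * thickness)
}

#' Closed-form surrogate radial profile
#'
#' @param thickness soft-tissue thickness, mm.
#' @param incidenceAngle beam incidence angle, degrees.
#' @param pars parameter list from \code{\link{surrogateParams}}.
#' @return a function \code{f(r)} giving intensity per mm^2 at radius r.
#' @export
surrogateProfile <- function(thickness, incidenceAngle = 0,
                             pars = surrogateParams()) {
  mu <- surrogateMu(thickness, incidenceAngle, pars)
  A <- surrogateAmplitude(thickness, pars)
  function(r) A * exp(-mu * r)
}

# analytic ring integrals of A*exp(-mu*r) over annuli: per-ring mean
# intensity and total in-ROI intensity (area-weighted), used by the
# feature-level dataset generator. radii = ring boundaries incl. 0.
surrogateRingMeans <- function(thickness, incidenceAngle, radii,
                               pars = surrogateParams()) {
  mu <- surrogateMu(thickness, incidenceAngle, pars)
  A <- surrogateAmplitude(thickness, pars)
  edges <- c(0, radii)
  # int_{r1}^{r2} exp(-mu r) 2 pi r dr
  ringInt <- function(r1, r2) {
    2 * pi / mu^2 * ((1 + mu * r1) * exp(-mu * r1) -
                     (1 + mu * r2) * exp(-mu * r2))
  }
  k <- seq_len(length(radii))
  tot <- A * ringInt(0, radii[length(radii)])
  means <- A * ringInt(edges[k], edges[k + 1]) /
    (pi * (edges[k + 1]^2 - edges[k]^2))
  list(means = means, total = tot)
}
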