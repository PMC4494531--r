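#' @include AllClasses.R
NULL

#' Construct optical properties
#'
#' @param mua absorption coefficient, 1/mm.
#' @param mus scattering coefficient, 1/mm.
#' @param g Henyey-Greenstein anisotropy, |g| < 1.
#' @param n refractive index.
#' @return an \linkS4class{OpticalProperties}.
#' @export
opticalProperties <- function(mua, mus, g = 0.9, n = 1.4) {
  new("OpticalProperties", mua = mua, mus = mus, g = g, n = n)
}

#' Default 850 nm optical properties
#'
#' Literature-plausible coefficients for scalp soft tissue and skull bone
#' at 850 nm. Bone is the brighter medium (lower \eqn{\mu_a/\mu_s'} than
#' soft tissue), which makes total backscatter decrease with overlying
#' soft-tissue thickness — the behaviour the thickness features rely on.
#'
#' @return an \linkS4class{OpticalProperties}.
#' @export
defaultTissueProperties <- function() {
  opticalProperties(mua = 0.01, mus = 10, g = 0.9, n = 1.4)
}

#' @rdname defaultTissueProperties
#' @export
defaultBoneProperties <- function() {
  opticalProperties(mua = 0.01, mus = 25, g = 0.9, n = 1.4)
}
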