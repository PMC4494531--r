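#' @include AllClasses.R
NULL

#' Construct a rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3 translation, mm.
#' @return a \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Rotation matrix about a unit axis
#'
#' Rodrigues construction of the rotation by \code{angle} radians about
#' \code{axis}.
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param points n x 3 matrix or length-3 vector, mm.
#' @return transformed points, same shape.
#' @export
applyTransform <- function(transform, points) {
  if (is.null(dim(points))) {
    return(as.numeric(transform@rotation %*% points + transform@translation))
  }
  sweep(points %*% t(transform@rotation), 2, transform@translation, "+")
}

#' Compose two rigid transforms
#'
#' Returns the transform applying \code{second} after \code{first}:
#' \code{y = R2 (R1 x + t1) + t2}.
#'
#' @param first,second \linkS4class{RigidTransform}s.
#' @return the composed \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(second, first) {
  rigidTransform(second@rotation %*% first@rotation,
                 as.numeric(second@rotation %*% first@translation +
                            second@translation))
}

#' Invert a rigid transform
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

#' Rotation angle of a rigid transform
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return the rotation angle, radians, in [0, pi].
#' @export
rotationAngle <- function(transform) {
  tr <- sum(diag(transform@rotation))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

#' Draw a random rigid transform
#'
#' Uniform random axis, rotation angle uniform in (0, \code{maxAngle}],
#' translation uniform in the cube of half-width \code{maxTranslation}.
#' Used for the phantom's ground-truth modality offset (defaults: rotation
#' at most 20 degrees, translation at most 50 mm per axis).
#'
#' @param maxAngle maximum rotation, degrees.
#' @param maxTranslation maximum per-axis translation, mm.
#' @return a \linkS4class{RigidTransform}.
#' @export
randomRigidTransform <- function(maxAngle = 20, maxTranslation = 50) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, maxAngle * pi / 180)
  rigidTransform(rotationAboutAxis(ax, ang),
                 runif(3, -maxTranslation, maxTranslation))
}

#' Serialize / read a rigid transform as JSON
#'
#' The JSON object carries the row-major rotation, the translation and a
#' \code{convention} tag, \code{"point-transform, y = R x + t"}.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param path file path.
#' @return \code{readTransformJSON} returns the \linkS4class{RigidTransform}.
#' @export
writeTransformJSON <- function(transform, path) {
  obj <- list(convention = "point-transform, y = R x + t",
              rotation = as.numeric(t(transform@rotation)),
              translation = transform@translation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformJSON
#' @export
readTransformJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(matrix(obj$rotation, 3, 3, byrow = TRUE),
                 obj$translation)
}
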