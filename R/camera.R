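#' @include AllClasses.R
NULL

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a pinhole camera looking at a target
#'
#' Builds the world-to-camera pose from a camera center, a look-at target
#' and an up hint; the camera z axis points toward the target.
#'
#' @param position camera center, world frame, mm.
#' @param lookAt target point, mm.
#' @param up up hint (not collinear with the viewing direction).
#' @param focalPx focal length, px.
#' @param principalPoint 2-vector, px.
#' @return a \linkS4class{CameraModel}.
#' @export
cameraLookingAt <- function(position, lookAt = c(0, 0, 0), up = c(0, 1, 0),
                            focalPx = 2000, principalPoint = c(512, 512)) {
  zc <- lookAt - position
  zc <- zc / sqrt(sum(zc^2))
  xc <- cross3(zc, up)
  xc <- xc / sqrt(sum(xc^2))
  yc <- cross3(zc, xc)
  R <- rbind(xc, yc, zc)
  dimnames(R) <- NULL
  new("CameraModel", focalPx = focalPx,
      principalPoint = as.numeric(principalPoint),
      pose = rigidTransform(R, as.numeric(-R %*% position)))
}

#' Default triangulation-camera geometry
#'
#' Camera 180 mm off the scanner axis at 480 mm standoff, looking at the
#' patch center; the baseline gives a triangulation angle of about 20
#' degrees.
#'
#' @return a \linkS4class{CameraModel}.
#' @export
defaultTriangulationCamera <- function() {
  cameraLookingAt(position = c(180, 0, 480))
}

#' Project world points into the camera
#'
#' @param camera a \linkS4class{CameraModel}.
#' @param points n x 3 matrix or length-3 vector, world mm.
#' @return n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @export
projectPoint <- function(camera, points) {
  single <- is.null(dim(points))
  p <- applyTransform(camera@pose, points)
  if (single) p <- matrix(p, 1, 3)
  if (any(p[, 3] <= 0)) stop("point behind the camera")
  px <- cbind(camera@focalPx * p[, 1] / p[, 3] + camera@principalPoint[1],
              camera@focalPx * p[, 2] / p[, 3] + camera@principalPoint[2])
  if (single) as.numeric(px) else px
}

#' Back-project a pixel into a world ray
#'
#' @param camera a \linkS4class{CameraModel}.
#' @param pixel length-2 pixel coordinate.
#' @return list with \code{origin} (camera center, mm) and unit
#'   \code{direction}.
#' @export
backprojectRay <- function(camera, pixel) {
  Rt <- t(camera@pose@rotation)
  center <- as.numeric(-Rt %*% camera@pose@translation)
  d <- c((pixel[1] - camera@principalPoint[1]) / camera@focalPx,
         (pixel[2] - camera@principalPoint[2]) / camera@focalPx, 1)
  d <- as.numeric(Rt %*% d)
  list(origin = center, direction = d / sqrt(sum(d^2)))
}

#' Construct a galvo calibration for a regular grid
#'
#' Deflection angles are chosen so adjacent columns and rows land
#' \code{colSpacing} / \code{rowSpacing} mm apart on the plane z = 0 at the
#' working distance; the central index points down the boresight (-z).
#'
#' @param gridRows,gridCols grid dimensions.
#' @param colSpacing,rowSpacing target-plane spacings, mm.
#' @param pivot galvo pivot point, mm (default (0, 0, 500)).
#' @return a \linkS4class{GalvoCalibration}.
#' @export
galvoCalibrationForGrid <- function(gridRows = 32L, gridCols = 32L,
                                    colSpacing = 1.5, rowSpacing = 1.0,
                                    pivot = c(0, 0, 500)) {
  D <- pivot[3]
  colOff <- (seq_len(gridCols) - (gridCols + 1) / 2) * colSpacing
  rowOff <- (seq_len(gridRows) - (gridRows + 1) / 2) * rowSpacing
  new("GalvoCalibration", pivot = as.numeric(pivot),
      colAngles = atan(colOff / D), rowAngles = atan(rowOff / D))
}

#' Laser ray for a grid index
#'
#' @param calib a \linkS4class{GalvoCalibration}.
#' @param row,col 1-based grid indices.
#' @return list with \code{origin} (pivot, mm) and unit \code{direction}.
#' @export
galvoRay <- function(calib, row, col) {
  if (row < 1 || row > length(calib@rowAngles) ||
      col < 1 || col > length(calib@colAngles)) {
    stop("grid index out of the configured grid")
  }
  d <- c(tan(calib@colAngles[col]), tan(calib@rowAngles[row]), -1)
  list(origin = calib@pivot, direction = d / sqrt(sum(d^2)))
}
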