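#' @include AllClasses.R
NULL

#' Two-ray triangulation by the midpoint method
#'
#' Intersects the laser ray with the camera ray back-projected through the
#' detected pixel: the returned point is the midpoint of the common
#' perpendicular of the two rays, and the residual is their distance at
#' closest approach — a direct quality metric that is 0 for a noiseless
#' observation.
#'
#' @param laserRay list with \code{origin} and unit \code{direction} (from
#'   \code{\link{galvoRay}}).
#' @param camera a \linkS4class{CameraModel}.
#' @param pixel length-2 pixel coordinate of the spot centroid.
#' @return list with \code{point} (mm) and \code{residual} (mm).
#' @export
triangulatePoint <- function(laserRay, camera, pixel) {
  camRay <- backprojectRay(camera, pixel)
  rayMidpoint(laserRay, camRay)
}

# closed-form closest approach of two rays
rayMidpoint <- function(ray1, ray2) {
  d1 <- ray1$direction / sqrt(sum(ray1$direction^2))
  d2 <- ray2$direction / sqrt(sum(ray2$direction^2))
  b <- sum(d1 * d2)
  if (abs(b) > cos(0.1 * pi / 180)) {
    stop("degenerate geometry: rays are near-parallel")
  }
  w <- ray2$origin - ray1$origin
  den <- 1 - b^2
  t1 <- (sum(w * d1) - b * sum(w * d2)) / den
  t2 <- (b * sum(w * d1) - sum(w * d2)) / den
  p1 <- ray1$origin + t1 * d1
  p2 <- ray2$origin + t2 * d2
  list(point = (p1 + p2) / 2, residual = sqrt(sum((p1 - p2)^2)))
}

# smallest-eigenvector normals from a k-nearest-neighbour plane fit,
# oriented toward `toward`
estimateNormals <- function(points, k = 8L, toward) {
  n <- nrow(points)
  k <- min(k, n - 1L)
  D <- as.matrix(dist(points))
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k + 1L)]   # self + k neighbours
    P <- points[nb, , drop = FALSE]
    C <- cov(P)
    ev <- eigen(C, symmetric = TRUE)
    v <- ev$vectors[, 3]
    if (sum(v * (toward - points[i, ])) < 0) v <- -v
    normals[i, ] <- v
  }
  normals
}

#' Reconstruct the 3D surface from a scan
#'
#' Triangulates every valid spot from its galvo ray and triangulation-
#' camera pixel, then estimates per-point surface normals by a local plane
#' fit (smallest-eigenvalue eigenvector of the scatter of the 8 nearest
#' neighbours), oriented toward the galvo pivot.
#'
#' @param scan a \linkS4class{NIRScan}.
#' @param calib \linkS4class{GalvoCalibration}; defaults to the scan's.
#' @param camera \linkS4class{CameraModel}; defaults to the scan's.
#' @param k neighbours for the normal plane fit.
#' @return a \linkS4class{SurfacePointCloud} with one row per valid spot,
#'   in scan-table order.
#' @export
reconstructScan <- function(scan, calib = scan@galvo,
                            camera = scan@camera, k = 8L) {
  meta <- scan@meta
  sel <- which(meta$valid)
  if (length(sel) < 3L) stop("cannot reconstruct: fewer than 3 valid spots")
  pts <- matrix(0, length(sel), 3)
  res <- numeric(length(sel))
  for (j in seq_along(sel)) {
    i <- sel[j]
    ray <- galvoRay(calib, meta$row[i], meta$col[i])
    tri <- triangulatePoint(ray, camera, c(meta$tri_px[i], meta$tri_py[i]))
    pts[j, ] <- tri$point
    res[j] <- tri$residual
  }
  normals <- estimateNormals(pts, k = k, toward = calib@pivot)
  new("SurfacePointCloud", points = pts, normals = normals,
      residuals = res,
      gridIndex = cbind(row = meta$row[sel], col = meta$col[sel]))
}
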