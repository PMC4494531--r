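#' @include AllClasses.R
NULL

asPointMatrix <- function(x) {
  if (is(x, "SurfacePointCloud")) return(x@points)
  if (is(x, "MRIThicknessMap")) return(x@points)
  if (is(x, "Tomogram4D")) return(x@points)
  m <- as.matrix(x)
  stopifnot(ncol(m) == 3)
  unname(m)
}

# least-squares rigid fit src -> dst (matched rows) via Kabsch/SVD
kabsch <- function(src, dst) {
  sc <- colMeans(src); dc <- colMeans(dst)
  H <- crossprod(sweep(src, 2, sc), sweep(dst, 2, dc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigidTransform(R, as.numeric(dc - R %*% sc))
}

#' Marker-based rigid pre-alignment
#'
#' Least-squares rigid fit of the source marker centroids onto the
#' destination centroids over shared labels, by the orthogonal-Procrustes
#' (Kabsch) construction: SVD of the label-matched cross-covariance with a
#' determinant correction, so the result is always a proper rotation. This
#' is the tracked-marker pre-alignment that initializes the ICP
#' refinement.
#'
#' @param srcMarkers,dstMarkers data.frames with columns \code{label, x,
#'   y, z} (mm). At least 3 shared, non-collinear labels are required.
#' @return the \linkS4class{RigidTransform} mapping source to destination.
#' @export
landmarkAlign <- function(srcMarkers, dstMarkers) {
  shared <- intersect(srcMarkers$label, dstMarkers$label)
  if (length(shared) < 3L) {
    stop("need at least 3 shared marker labels")
  }
  s <- as.matrix(srcMarkers[match(shared, srcMarkers$label),
                            c("x", "y", "z")])
  d <- as.matrix(dstMarkers[match(shared, dstMarkers$label),
                            c("x", "y", "z")])
  sv <- svd(scale(s, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("markers are collinear: alignment is underdetermined")
  }
  kabsch(s, d)
}

#' Trimmed point-to-point ICP refinement
#'
#' Iterates exact nearest-neighbour correspondences under the current
#' transform, rejection of pairs beyond the correspondence distance cap
#' and of the worst \code{trimFraction} of the rest, and a closed-form
#' rigid (Kabsch) update, until the RMS change falls below the tolerance
#' or the iteration cap is reached. The returned transform maps source to
#' target and is already composed with the initialization; the reported
#' RMS is the trimmed point-to-nearest-correspondence RMS after the final
#' update — the matching-error metric.
#'
#' @param source source cloud (\linkS4class{SurfacePointCloud} or n x 3
#'   matrix), mm.
#' @param target target cloud (\linkS4class{MRIThicknessMap} or n x 3
#'   matrix), mm.
#' @param init initial \linkS4class{RigidTransform} (e.g. from
#'   \code{\link{landmarkAlign}}).
#' @param params an \linkS4class{ICPParams}.
#' @return a \linkS4class{RegistrationResult}.
#' @export
icpRefine <- function(source, target, init = rigidTransform(),
                      params = new("ICPParams")) {
  S <- asPointMatrix(source)
  T_ <- asPointMatrix(target)
  if (nrow(S) < 10L || nrow(T_) < 10L) {
    stop("both clouds must contain at least 10 points")
  }
  validObject(init); validObject(params)

  correspond <- function(transform) {
    St <- applyTransform(transform, S)
    nn <- nn1_cpp(St, T_)
    keep <- which(nn$dist <= params@maxCorrDist)
    if (length(keep) == 0L) {
      stop("divergence: correspondence set empty")
    }
    if (params@trimFraction > 0) {
      nDrop <- floor(params@trimFraction * length(keep))
      if (nDrop > 0) {
        ord <- order(nn$dist[keep], decreasing = TRUE)
        keep <- keep[-ord[seq_len(nDrop)]]
      }
    }
    list(src = keep, dst = nn$idx[keep], dist = nn$dist[keep])
  }

  cur <- init
  trace <- numeric(0)
  preTrace <- numeric(0)
  rmsPrev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < params@maxIterations) {
    iter <- iter + 1L
    co <- correspond(cur)
    preTrace <- c(preTrace, sqrt(mean(co$dist^2)))
    cur <- kabsch(S[co$src, , drop = FALSE], T_[co$dst, , drop = FALSE])
    post <- sqrt(mean(rowSums(
      (applyTransform(cur, S[co$src, , drop = FALSE]) -
         T_[co$dst, , drop = FALSE])^2)))
    trace <- c(trace, post)
    if (abs(rmsPrev - post) < params@rmsChangeTol) {
      converged <- TRUE
      break
    }
    rmsPrev <- post
  }
  final <- correspond(cur)
  new("RegistrationResult", transform = cur,
      rms = sqrt(mean(final$dist^2)), iterations = iter,
      converged = converged, trace = trace, preTrace = preTrace)
}

#' Transfer MRI thickness labels onto registered NIR points
#'
#' Each NIR surface point, mapped into the MRI frame, receives the
#' inverse-distance-weighted mean thickness of the MRI points within
#' \code{radius}; points with no MRI neighbour are returned as NA
#' (unlabeled). Labeling refuses to run when the registration RMS exceeds
#' the gate, preventing training on misaligned data.
#'
#' @param cloud NIR-frame cloud (\linkS4class{SurfacePointCloud} or n x 3
#'   matrix).
#' @param mri an \linkS4class{MRIThicknessMap}.
#' @param transform NIR-to-MRI \linkS4class{RigidTransform} (e.g. from
#'   \code{\link{icpRefine}}).
#' @param radius neighbourhood radius, mm (default 0.5).
#' @param registrationRMS the RMS of the registration that produced
#'   \code{transform}, mm.
#' @param gate maximum acceptable registration RMS, mm (default 1.0).
#' @return numeric thickness per NIR point, mm (NA = unlabeled), with the
#'   neighbour count as attribute \code{"count"}.
#' @export
transferThicknessLabels <- function(cloud, mri, transform = rigidTransform(),
                                    radius = 0.5, registrationRMS = 0,
                                    gate = 1.0) {
  if (registrationRMS > gate) {
    stop(sprintf(
      "registration gate exceeded: rms %.3f mm > gate %.3f mm; refusing to label",
      registrationRMS, gate))
  }
  P <- applyTransform(transform, asPointMatrix(cloud))
  res <- idw_radius_cpp(P, mri@points, mri@thickness, radius)
  out <- res$value
  attr(out, "count") <- res$count
  out
}
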