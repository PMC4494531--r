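#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small accessor family: \code{rotation}/\code{translation} for rigid
#' transforms, \code{cloudPoints}/\code{cloudNormals} for point clouds and
#' tomograms, \code{thicknessValues} for MRI maps and tomograms,
#' \code{hyperparams} for fitted GP models, \code{pooledRMS} and
#' \code{cvRecords} for cross-validation results, and \code{weightLedger}
#' for Monte-Carlo profiles.
#'
#' @param object an object of the documented classes.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases rotation translation cloudPoints cloudNormals thicknessValues
#'   hyperparams pooledRMS cvRecords weightLedger
NULL

#' @rdname accessors
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(object) standardGeneric("cloudPoints"))
#' @rdname accessors
#' @export
setGeneric("cloudNormals", function(object) standardGeneric("cloudNormals"))
#' @rdname accessors
#' @export
setGeneric("thicknessValues",
           function(object) standardGeneric("thicknessValues"))
#' @rdname accessors
#' @export
setGeneric("hyperparams", function(object) standardGeneric("hyperparams"))
#' @rdname accessors
#' @export
setGeneric("pooledRMS", function(object) standardGeneric("pooledRMS"))
#' @rdname accessors
#' @export
setGeneric("cvRecords", function(object) standardGeneric("cvRecords"))
#' @rdname accessors
#' @export
setGeneric("weightLedger", function(object) standardGeneric("weightLedger"))

#' @rdname accessors
setMethod("rotation", "RigidTransform", function(object) object@rotation)
#' @rdname accessors
setMethod("translation", "RigidTransform", function(object) object@translation)
#' @rdname accessors
setMethod("cloudPoints", "SurfacePointCloud", function(object) object@points)
#' @rdname accessors
setMethod("cloudPoints", "Tomogram4D", function(object) object@points)
#' @rdname accessors
setMethod("cloudPoints", "MRIThicknessMap", function(object) object@points)
#' @rdname accessors
setMethod("cloudNormals", "SurfacePointCloud", function(object) object@normals)
#' @rdname accessors
setMethod("thicknessValues", "MRIThicknessMap",
          function(object) object@thickness)
#' @rdname accessors
setMethod("thicknessValues", "Tomogram4D", function(object) object@thickness)
#' @rdname accessors
setMethod("hyperparams", "GPModel", function(object) object@hyper)
#' @rdname accessors
setMethod("pooledRMS", "CVResult", function(object) object@pooledRMS)
#' @rdname accessors
setMethod("cvRecords", "CVResult", function(object) object@records)
#' @rdname accessors
setMethod("weightLedger", "BackscatterProfile", function(object) object@ledger)

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf(
    "Phantom: %g x %g mm patch, thickness in [%g, %g] mm, %d markers (seed %d)\n",
    object@patchSize[1], object@patchSize[2], object@thicknessRange[1],
    object@thicknessRange[2], nrow(object@markers), object@seed))
})

setMethod("show", "BackscatterProfile", function(object) {
  l <- object@ledger
  cat(sprintf(
    "BackscatterProfile: %g photons, %.4f exited / %.4f absorbed / %.4f killed, max exit depth %.2f mm\n",
    object@nPhotons, l["exited"] / l["launched"],
    l["absorbed"] / l["launched"], l["killed"] / l["launched"],
    object@maxDepthExit))
})

setMethod("show", "SurfacePointCloud", function(object) {
  cat(sprintf("SurfacePointCloud: %d points, median residual %.2g mm\n",
              nrow(object@points),
              if (nrow(object@points)) median(object@residuals) else NA))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: rms %.4f mm after %d iterations (%s)\n",
              object@rms, object@iterations,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "GPModel", function(object) {
  hp <- object@hyper
  cat(sprintf(
    "GPModel: n = %d, d = %d | sigma_f^2 = %.3g, sigma_n^2 = %.3g, lml = %.2f\n",
    nrow(object@X), ncol(object@X), hp@signalVariance, hp@noiseVariance,
    object@objective))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d repeats x %d folds, %d test records | pooled RMS %.4f mm (mean fold RMS %.4f mm)\n",
    object@nRepeats, object@nFolds, nrow(object@records), object@pooledRMS,
    object@meanFoldRMS))
})

setMethod("show", "Tomogram4D", function(object) {
  cat(sprintf(
    "Tomogram4D: %d points, thickness %.2f-%.2f mm, %d clipped\n",
    nrow(object@points),
    if (nrow(object@points)) min(object@thickness) else NA,
    if (nrow(object@points)) max(object@thickness) else NA,
    object@nClipped))
})
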