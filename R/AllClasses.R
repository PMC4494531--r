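#' @import methods
#' @importFrom stats rnorm runif sd median quantile optim dist cor cov
#'   uniroot rlnorm var aggregate
#' @importFrom utils write.csv read.csv read.table head modifyList
#' @importFrom tools md5sum
#' @useDynLib nirtomo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Rigid transform between metric 3D frames
#'
#' A proper rigid transform acting on points as \eqn{y = R x + t}, with
#' \eqn{R} a 3x3 rotation matrix and \eqn{t} a translation in mm. Used for
#' the camera pose, the phantom's ground-truth NIR-to-MRI modality offset,
#' and all registration outputs.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3 translation, mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    return("rotation must be orthonormal to 1e-9")
  }
  if (abs(det(R) - 1) > 1e-9) return("det(rotation) must be +1")
  TRUE
})

#' Optical properties of a homogeneous medium at the scan wavelength
#'
#' Absorption and scattering coefficients in per-mm, Henyey-Greenstein
#' anisotropy, and refractive index (metadata; the transport model uses a
#' matched-index top boundary).
#'
#' @slot mua absorption coefficient, 1/mm (>= 0).
#' @slot mus scattering coefficient, 1/mm (> 0).
#' @slot g scattering anisotropy, |g| < 1.
#' @slot n refractive index (>= 1).
#' @export
setClass("OpticalProperties",
  representation(mua = "numeric", mus = "numeric", g = "numeric",
                 n = "numeric"),
  prototype(mua = 0.01, mus = 10, g = 0.9, n = 1.4))

setValidity("OpticalProperties", function(object) {
  if (object@mua < 0) return("mua must be >= 0")
  if (object@mus <= 0) return("mus must be > 0")
  if (abs(object@g) >= 1) return("|g| must be < 1")
  if (object@n < 1) return("n must be >= 1")
  TRUE
})

#' Laser-grid scan configuration
#'
#' Geometry and noise settings of one grid scan: a \code{gridRows} x
#' \code{gridCols} point grid (default 32x32) with column spacing 1.5 mm and
#' row spacing 1.0 mm on the target at the working distance, spot diameter
#' 1.3 mm, and the imaging/noise parameters of the co-axial HDR camera.
#'
#' @slot gridRows,gridCols grid dimensions (default 32 x 32).
#' @slot colSpacing,rowSpacing target-plane spacing between adjacent
#'   columns/rows, mm (defaults 1.5 / 1.0).
#' @slot spotDiameter laser spot diameter, mm (default 1.3).
#' @slot wavelength nm, metadata only (default 850).
#' @slot photonsPerSpot photon count for Monte-Carlo spot profiles.
#' @slot rngSeed integer seed recorded with every simulated product.
#' @slot pixelPitch HDR image pixel pitch, mm/px.
#' @slot imageSize HDR image side length, px (square images).
#' @slot noiseCV multiplicative (log-normal) pixel noise coefficient of
#'   variation; 0 disables.
#' @slot backgroundSD additive background (read) noise SD, image units.
#' @slot snrThreshold peak-over-background-noise validity threshold.
#' @slot profileModel "surrogate" (closed-form radial profile family) or
#'   "mc" (Monte-Carlo profile library interpolated across thickness).
#' @slot profileKnots thickness knots for the "mc" profile library, mm.
#' @slot profileParams parameter list of the surrogate profile family (see
#'   \code{\link{surrogateParams}}).
#' @export
setClass("ScanConfig",
  representation(gridRows = "integer", gridCols = "integer",
                 colSpacing = "numeric", rowSpacing = "numeric",
                 spotDiameter = "numeric", wavelength = "numeric",
                 photonsPerSpot = "integer", rngSeed = "integer",
                 pixelPitch = "numeric", imageSize = "integer",
                 noiseCV = "numeric", backgroundSD = "numeric",
                 snrThreshold = "numeric", profileModel = "character",
                 profileKnots = "numeric", profileParams = "list"))

setValidity("ScanConfig", function(object) {
  if (object@gridRows < 1L || object@gridCols < 1L) {
    return("grid dimensions must be positive")
  }
  if (object@colSpacing <= 0 || object@rowSpacing <= 0) {
    return("grid spacings must be > 0")
  }
  if (object@spotDiameter <= 0) return("spot diameter must be > 0")
  if (object@pixelPitch <= 0) return("pixel pitch must be > 0")
  if (!object@profileModel %in% c("surrogate", "mc")) {
    return("profileModel must be 'surrogate' or 'mc'")
  }
  TRUE
})

#' Synthetic forehead-like phantom
#'
#' The ground truth every downstream stage is tested against: a smooth
#' curved surface patch \eqn{z(x, y)}, a soft-tissue thickness field
#' \eqn{d(x, y)} over bone, layered optical properties, rigidly attached
#' fiducial markers, and the ground-truth rigid transform into the MRI
#' frame. The surface is a low-order dome plus a band-limited cosine random
#' field, so heights, gradients and normals are analytic.
#'
#' @slot patchSize extent of the rectangular patch, mm (x, y); the patch is
#'   centred on the origin.
#' @slot surface parameter list of the height field (dome curvature plus
#'   cosine-series coefficients).
#' @slot thicknessField parameter list of the thickness field.
#' @slot thicknessRange clamp range of the thickness field, mm.
#' @slot tissueProps,boneProps \linkS4class{OpticalProperties} of the two
#'   layers.
#' @slot markers data.frame with columns label, x, y, z (mm, NIR frame).
#' @slot mriTransform ground-truth \linkS4class{RigidTransform} mapping the
#'   NIR frame into the MRI frame.
#' @slot seed integer seed the phantom was generated from.
#' @export
setClass("Phantom",
  representation(patchSize = "numeric", surface = "list",
                 thicknessField = "list", thicknessRange = "numeric",
                 tissueProps = "OpticalProperties",
                 boneProps = "OpticalProperties",
                 markers = "data.frame", mriTransform = "RigidTransform",
                 seed = "integer"))

setValidity("Phantom", function(object) {
  if (length(object@thicknessRange) != 2L ||
      object@thicknessRange[1] < 0 ||
      diff(object@thicknessRange) < 0) {
    return("thicknessRange must be 0 <= min <= max")
  }
  m <- object@markers
  if (nrow(m) < 3L) return("at least 3 markers required")
  p <- as.matrix(m[, c("x", "y", "z")])
  if (nrow(p) >= 3L) {
    s <- svd(scale(p, scale = FALSE))$d
    if (s[2] < 1e-6) return("markers must not be collinear")
  }
  TRUE
})

#' Radial backscatter profile from the photon-transport model
#'
#' Result of one Monte-Carlo run: per-photon-normalized exit weight binned
#' by exit distance from the beam axis, the photon weight ledger, and the
#' distribution of the maximum depth visited among photons that exited
#' through the top surface.
#'
#' @slot binEdges radial bin edges, mm (last bin is overflow).
#' @slot weights exit weight per radial bin divided by launched photons.
#' @slot ledger named numeric: launched, exited, absorbed, killed, lost.
#' @slot depthEdges,depthHist exit-weighted histogram of per-photon maximum
#'   depth, mm.
#' @slot maxDepthExit maximum depth visited by any exiting photon, mm.
#' @slot nPhotons,nExited launched and exiting photon counts.
#' @export
setClass("BackscatterProfile",
  representation(binEdges = "numeric", weights = "numeric",
                 ledger = "numeric", depthEdges = "numeric",
                 depthHist = "numeric", maxDepthExit = "numeric",
                 nPhotons = "numeric", nExited = "numeric"))

#' MRI-like ground-truth thickness map
#'
#' Surface point set in the MRI frame sampled anisotropically (default
#' 0.15 mm in-plane, 1 mm out-of-plane), per-point soft-tissue thickness
#' with segmentation noise, and labeled marker centroids with localization
#' noise.
#'
#' @slot points n x 3 surface points, mm, MRI frame.
#' @slot thickness thickness per point, mm.
#' @slot markers data.frame with columns label, x, y, z (MRI frame).
#' @export
setClass("MRIThicknessMap",
  representation(points = "matrix", thickness = "numeric",
                 markers = "data.frame"))

setValidity("MRIThicknessMap", function(object) {
  if (nrow(object@points) != length(object@thickness)) {
    return("points and thickness must have the same cardinality")
  }
  TRUE
})

#' Pinhole model of the triangulation camera
#'
#' Distortion-free pinhole with focal length in pixels, principal point,
#' and a world-to-camera rigid pose.
#'
#' @slot focalPx focal length, px.
#' @slot principalPoint 2-vector, px.
#' @slot pose \linkS4class{RigidTransform}, world -> camera.
#' @export
setClass("CameraModel",
  representation(focalPx = "numeric", principalPoint = "numeric",
                 pose = "RigidTransform"))

setValidity("CameraModel", function(object) {
  if (object@focalPx <= 0) return("focal length must be > 0")
  if (length(object@principalPoint) != 2L) {
    return("principal point must be length 2")
  }
  TRUE
})

#' Galvanometric scanner calibration
#'
#' Deflection model of the laser scanner: a pivot point and per-grid-index
#' deflection angles about the two mirror axes. Rays leave the pivot along
#' \code{(tan(colAngle), tan(rowAngle), -1)}, normalized; the boresight
#' (central index) points down the -z axis toward the phantom.
#'
#' @slot pivot 3D pivot point, mm.
#' @slot colAngles,rowAngles deflection angles per column/row, radians.
#' @export
setClass("GalvoCalibration",
  representation(pivot = "numeric", colAngles = "numeric",
                 rowAngles = "numeric"))

#' Triangulated surface point cloud
#'
#' Per-valid-spot 3D points reconstructed by two-ray triangulation,
#' local-plane-fit normals oriented toward the scanner, and the
#' ray-to-ray closest-approach residual of each triangulation.
#'
#' @slot points n x 3 points, mm.
#' @slot normals n x 3 unit normals.
#' @slot residuals triangulation residual per point, mm.
#' @slot gridIndex n x 2 integer matrix of (row, col) grid indices.
#' @export
setClass("SurfacePointCloud",
  representation(points = "matrix", normals = "matrix",
                 residuals = "numeric", gridIndex = "matrix"))

setValidity("SurfacePointCloud", function(object) {
  n <- nrow(object@points)
  if (nrow(object@normals) != n || length(object@residuals) != n) {
    return("points, normals and residuals must align")
  }
  if (n > 0) {
    nrm <- sqrt(rowSums(object@normals^2))
    if (max(abs(nrm - 1)) > 1e-6) return("normals must be unit length")
    if (any(object@residuals < 0)) return("residuals must be >= 0")
  }
  TRUE
})

#' Iterative-closest-point settings
#'
#' @slot maxIterations iteration cap.
#' @slot rmsChangeTol convergence tolerance on the RMS change, mm.
#' @slot maxCorrDist correspondence rejection distance, mm.
#' @slot trimFraction fraction of worst correspondences dropped, in [0, 0.5).
#' @export
setClass("ICPParams",
  representation(maxIterations = "integer", rmsChangeTol = "numeric",
                 maxCorrDist = "numeric", trimFraction = "numeric"),
  prototype(maxIterations = 100L, rmsChangeTol = 1e-4, maxCorrDist = 5,
            trimFraction = 0.1))

setValidity("ICPParams", function(object) {
  if (object@rmsChangeTol <= 0) return("tolerance must be > 0")
  if (object@trimFraction < 0 || object@trimFraction >= 0.5) {
    return("trimFraction must lie in [0, 0.5)")
  }
  TRUE
})

#' Registration outcome
#'
#' @slot transform final \linkS4class{RigidTransform} (composed with the
#'   initialization), mapping source into target frame.
#' @slot rms final point-to-correspondence RMS, mm.
#' @slot iterations iterations executed.
#' @slot converged logical.
#' @slot trace per-iteration RMS after each rigid update.
#' @slot preTrace per-iteration RMS on the same correspondences before the
#'   update (the update never increases it).
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", rms = "numeric",
                 iterations = "integer", converged = "logical",
                 trace = "numeric", preTrace = "numeric"))

setValidity("RegistrationResult", function(object) {
  if (object@rms < 0) return("rms must be >= 0")
  TRUE
})

#' ARD kernel hyperparameters
#'
#' Squared-exponential automatic-relevance-determination kernel:
#' \deqn{k(x, x') = \sigma_f^2 \exp(-\tfrac12 \sum_d (x_d - x'_d)^2 /
#' \ell_d^2)} plus observation noise \eqn{\sigma_n^2}. Length-scales are in
#' standardized-feature units.
#'
#' @slot signalVariance \eqn{\sigma_f^2}, squared target units.
#' @slot lengthScales \eqn{\ell_d}, one per feature dimension.
#' @slot noiseVariance \eqn{\sigma_n^2}, squared target units.
#' @export
setClass("GPHyperparams",
  representation(signalVariance = "numeric", lengthScales = "numeric",
                 noiseVariance = "numeric"))

setValidity("GPHyperparams", function(object) {
  if (object@signalVariance <= 0 || object@noiseVariance <= 0 ||
      any(object@lengthScales <= 0)) {
    return("all hyperparameters must be strictly positive")
  }
  TRUE
})

#' Trained Gaussian-process regression model
#'
#' Stores the standardized training set, fitted hyperparameters, the lower
#' Cholesky factor of \eqn{K + \sigma_n^2 I} and the precomputed solve
#' against the centered targets, i.e. everything prediction needs.
#'
#' @slot X standardized n x d training features.
#' @slot y centered training targets, mm.
#' @slot xCenter,xScale per-dimension standardization of the features.
#' @slot yCenter training-target mean, mm.
#' @slot hyper \linkS4class{GPHyperparams}.
#' @slot L lower-triangular Cholesky factor of \eqn{K + \sigma_n^2 I}.
#' @slot alpha solve of the factorization against \code{y}.
#' @slot objective final log marginal likelihood.
#' @slot trace objective value at each accepted optimizer improvement.
#' @export
setClass("GPModel",
  representation(X = "matrix", y = "numeric", xCenter = "numeric",
                 xScale = "numeric", yCenter = "numeric",
                 hyper = "GPHyperparams", L = "matrix", alpha = "numeric",
                 objective = "numeric", trace = "numeric"))

#' Cross-validation result
#'
#' Inverse repeated k-fold scheme: per repeat the data are shuffled into
#' \code{nFolds} near-equal folds; the model is trained on each single fold
#' and predicts the remaining folds, so every sample is tested
#' \code{nFolds - 1} times per repeat.
#'
#' @slot records per-sample test records: repeat index, training fold,
#'   sample index, prediction, truth.
#' @slot pooledRMS RMS over all test records, mm (the reported metric).
#' @slot foldRMS per (repeat, fold) RMS, mm.
#' @slot meanFoldRMS mean of the per-fold RMS values, mm.
#' @slot nFolds,nRepeats,seed scheme parameters.
#' @export
setClass("CVResult",
  representation(records = "data.frame", pooledRMS = "numeric",
                 foldRMS = "data.frame", meanFoldRMS = "numeric",
                 nFolds = "integer", nRepeats = "integer", seed = "integer"))

#' 4D tomogram
#'
#' Surface point cloud augmented with the predicted soft-tissue thickness
#' beneath each point and its predictive variance; negative predicted means
#' are clipped to 0 and counted.
#'
#' @slot points n x 3 surface points, mm.
#' @slot thickness predicted thickness per point, mm (>= 0 after clipping).
#' @slot thicknessVariance predictive variance, mm^2.
#' @slot nClipped number of negative predictions clipped to 0.
#' @slot provenance list: config hash, seeds, registration RMS.
#' @export
setClass("Tomogram4D",
  representation(points = "matrix", thickness = "numeric",
                 thicknessVariance = "numeric", nClipped = "integer",
                 provenance = "list"))

setValidity("Tomogram4D", function(object) {
  n <- nrow(object@points)
  if (length(object@thickness) != n ||
      length(object@thicknessVariance) != n) {
    return("parallel arrays must have equal cardinality")
  }
  if (n > 0 && any(object@thickness < 0)) {
    return("thickness must be >= 0 after clipping")
  }
  TRUE
})
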