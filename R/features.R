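#' @include AllClasses.R
NULL

#' Concentric-annulus feature layout
#'
#' Ring boundaries (mm) around the spot centroid. The default six rings
#' start at the laser spot radius (0.65 mm) and extend to 6.5 mm;
#' \code{normalization = "total"} divides each ring mean by the total
#' intensity inside the outermost radius, making the features invariant to
#' global intensity scale.
#'
#' @param radii strictly increasing positive ring boundary radii, mm; ring
#'   k spans [radii[k-1], radii[k]) with an implicit inner boundary at 0.
#' @param normalization \code{"total"} or \code{"none"}.
#' @return a validated list of class \code{"AnnulusSpec"}.
#' @export
annulusSpec <- function(radii = c(0.65, 1.3, 2.0, 3.0, 4.5, 6.5),
                        normalization = c("total", "none")) {
  normalization <- match.arg(normalization)
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("radii must be strictly increasing and positive")
  }
  structure(list(radii = radii, normalization = normalization),
            class = "AnnulusSpec")
}

#' Intensity-weighted spot centroid
#'
#' Background (the median of the border pixels) is subtracted and negative
#' residuals clamped before weighting. Coordinates are 0-based with the
#' origin at the top-left pixel center, returned as (row, col).
#'
#' @param image HDR image matrix.
#' @return length-2 numeric (row, col), px.
#' @export
computeCentroid <- function(image) {
  n1 <- nrow(image); n2 <- ncol(image)
  border <- c(image[1, ], image[n1, ], image[, 1], image[, n2])
  w <- pmax(image - median(border), 0)
  s <- sum(w)
  if (s <= 0) stop("empty spot: no pixel above background")
  rows <- matrix(seq_len(n1) - 1, n1, n2)
  cols <- matrix(seq_len(n2) - 1, n1, n2, byrow = TRUE)
  c(sum(rows * w), sum(cols * w)) / s
}

#' Peak signal-to-noise ratio of a spot image
#'
#' Peak minus background (median of the border pixels) over the border
#' noise SD, computed on a 3x3 box-smoothed copy of the image so the peak
#' estimate is not captured by single-pixel noise spikes. The validity
#' rule keeps spots with SNR at or above the configured threshold.
#'
#' @param image HDR image matrix.
#' @return scalar SNR (large for a noiseless image with signal).
#' @export
spotSNR <- function(image) {
  n1 <- nrow(image); n2 <- ncol(image)
  if (n1 >= 3 && n2 >= 3) {
    # 3x3 box filter by running sums
    cs <- function(m) {
      a <- m[seq_len(nrow(m) - 2), ] + m[seq_len(nrow(m) - 2) + 1, ] +
        m[seq_len(nrow(m) - 2) + 2, ]
      (a[, seq_len(ncol(m) - 2)] + a[, seq_len(ncol(m) - 2) + 1] +
         a[, seq_len(ncol(m) - 2) + 2]) / 9
    }
    sm <- cs(image)
  } else {
    sm <- image
  }
  border <- c(sm[1, ], sm[nrow(sm), ], sm[, 1], sm[, ncol(sm)])
  bg <- median(border)
  s <- sd(border)
  (max(sm) - bg) / max(s, 1e-12)
}

#' Per-ring mean intensities around a centroid
#'
#' Pixels are assigned to ring k when their center distance from the
#' centroid (in mm, via \code{pixelPitch}) lies in [r_{k-1}, r_k); ring 1
#' starts at 0. With \code{"total"} normalization each ring mean is
#' divided by the total intensity inside the outermost radius.
#'
#' @param image HDR image matrix.
#' @param centroid (row, col) 0-based centroid, px.
#' @param spec an \code{\link{annulusSpec}}.
#' @param pixelPitch mm per pixel.
#' @return numeric vector of ring features, one per ring.
#' @export
extractAnnulusFeatures <- function(image, centroid, spec = annulusSpec(),
                                   pixelPitch) {
  stopifnot(inherits(spec, "AnnulusSpec"), pixelPitch > 0)
  radii <- spec$radii
  n1 <- nrow(image); n2 <- ncol(image)
  rmax <- radii[length(radii)]
  edge <- pixelPitch * min(centroid[1], n1 - 1 - centroid[1],
                           centroid[2], n2 - 1 - centroid[2])
  if (rmax > edge + 1e-9) {
    stop("outermost radius does not fit inside the image")
  }
  rows <- matrix(seq_len(n1) - 1, n1, n2)
  cols <- matrix(seq_len(n2) - 1, n1, n2, byrow = TRUE)
  d <- pixelPitch * sqrt((rows - centroid[1])^2 + (cols - centroid[2])^2)
  edges <- c(0, radii)
  means <- numeric(length(radii))
  for (k in seq_along(radii)) {
    sel <- d >= edges[k] & d < edges[k + 1]
    if (!any(sel)) stop("ring too thin for pitch: ring ", k, " is empty")
    means[k] <- mean(image[sel])
  }
  if (spec$normalization == "total") {
    tot <- sum(image[d < rmax])
    if (tot == 0) stop("empty spot: zero total intensity in ROI")
    means <- means / tot
  }
  means
}

#' Incident angle between beam and surface normal
#'
#' Arc-cosine of the absolute normalized dot product, in degrees; always
#' in [0, 90].
#'
#' @param normal surface normal (any nonzero length-3 vector).
#' @param beam beam direction (any nonzero length-3 vector).
#' @return angle in degrees.
#' @export
computeIncidentAngle <- function(normal, beam) {
  nn <- sqrt(sum(normal^2)); nb <- sqrt(sum(beam^2))
  if (nn == 0 || nb == 0) stop("zero vector has no direction")
  acos(min(1, abs(sum(normal * beam)) / (nn * nb))) * 180 / pi
}

#' Assemble the optical feature table of a scan
#'
#' Runs centroid detection, annulus feature extraction and the SNR validity
#' rule over every spot of a scan and returns one row per grid point with
#' the feature columns \code{f1..fK}, the incident-angle feature, the
#' thickness label, the validity flag and a rejection reason
#' (\code{"miss"}, \code{"low_snr"}, \code{"centroid"}, \code{"ring"}, or
#' \code{""} for valid rows). Valid count plus rejected count always equals
#' the total spot count.
#'
#' @param scan a \linkS4class{NIRScan}.
#' @param spec an \code{\link{annulusSpec}}.
#' @param snrThreshold validity threshold; defaults to the scan config.
#' @param labels \code{NULL} to take labels from the synthetic ground truth
#'   carried by the scan, or a numeric vector (one per spot, NA allowed)
#'   from a registered MRI lookup.
#' @return data.frame with columns \code{row, col, f1..fK, angle_deg,
#'   thickness_mm, valid, reject_reason}.
#' @export
assembleFeatureTable <- function(scan, spec = annulusSpec(),
                                 snrThreshold = scan@config@snrThreshold,
                                 labels = NULL) {
  meta <- scan@meta
  n <- nrow(meta)
  if (n == 0) stop("scan is empty")
  K <- length(spec$radii)
  feat <- matrix(NA_real_, n, K)
  valid <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    if (!meta$hit[i]) { reason[i] <- "miss"; next }
    if (meta$snr[i] < snrThreshold) { reason[i] <- "low_snr"; next }
    img <- scan@images[[i]]
    cen <- tryCatch(computeCentroid(img), error = function(e) NULL)
    if (is.null(cen)) { reason[i] <- "centroid"; next }
    f <- tryCatch(
      extractAnnulusFeatures(img, cen, spec, scan@config@pixelPitch),
      error = function(e) NULL)
    if (is.null(f)) { reason[i] <- "ring"; next }
    feat[i, ] <- f
    valid[i] <- TRUE
  }
  lab <- if (is.null(labels)) meta$thickness else as.numeric(labels)
  out <- data.frame(row = meta$row, col = meta$col)
  for (k in seq_len(K)) out[[paste0("f", k)]] <- feat[, k]
  out$angle_deg <- meta$angle_deg
  out$thickness_mm <- lab
  out$valid <- valid
  out$reject_reason <- reason
  if (!any(valid)) stop("no valid data: all spots rejected")
  out
}

#' Write / read a feature table as CSV
#'
#' Column order is fixed: \code{row, col, f1..fK, angle_deg, thickness_mm,
#' valid, reject_reason}; missing labels are written as empty fields.
#'
#' @param table a feature table from \code{\link{assembleFeatureTable}}.
#' @param path file path.
#' @return \code{readFeatureCSV} returns the data.frame.
#' @export
writeFeatureCSV <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$reject_reason[is.na(out$reject_reason)] <- ""
  out
}
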