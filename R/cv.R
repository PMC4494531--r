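#' @include AllClasses.R
NULL

#' Extract the GP design matrix from a feature table
#'
#' Keeps valid rows with finite labels and returns the annulus features
#' (plus, by default, the incident-angle feature) and the thickness
#' labels.
#'
#' @param table feature table from \code{\link{assembleFeatureTable}} or
#'   \code{\link{makeSubjectDataset}}.
#' @param includeAngle include \code{angle_deg} as an extra feature
#'   dimension.
#' @return list with matrix \code{X}, vector \code{y} (mm) and the kept
#'   row indices \code{rows}.
#' @export
featureMatrix <- function(table, includeAngle = TRUE) {
  fcols <- grep("^f[0-9]+$", names(table), value = TRUE)
  keep <- which(table$valid & is.finite(table$thickness_mm))
  X <- as.matrix(table[keep, fcols, drop = FALSE])
  if (includeAngle) X <- cbind(X, angle_deg = table$angle_deg[keep])
  list(X = unname(X), y = table$thickness_mm[keep], rows = keep)
}

# seeded partition into near-equal folds; depends only on (seed, n)
foldPartition <- function(n, nFolds, seed) {
  stopifnot(n >= nFolds)
  for (attempt in 1:10) {
    folds <- withSeed(as.integer(seed) + (attempt - 1L) * 104729L, {
      idx <- sample.int(n)
      split(idx, rep(seq_len(nFolds), length.out = n))
    })
    if (all(lengths(folds) >= 2L)) return(folds)
    message("fold smaller than 2 samples; reshuffling partition")
  }
  stop("could not build a partition with all folds >= 2 samples")
}

#' Inverse repeated tenfold cross-validation of the GP
#'
#' The evaluation scheme of the thickness estimator: per repeat the
#' samples are shuffled into \code{nFolds} near-equal folds; for each fold
#' the GP is trained on that single fold (hyperparameters refit by
#' marginal-likelihood ascent) and predicts all remaining folds. Every
#' sample is therefore tested exactly \code{nFolds - 1} times per repeat.
#' The pooled RMS over all test records is the reported metric; the mean
#' of per-fold RMS values is returned alongside.
#'
#' @param X n x d feature matrix.
#' @param y length-n thickness labels, mm.
#' @param nFolds folds per repeat (default 10).
#' @param nRepeats repeats (default 5); repeat r uses seed + r - 1 for its
#'   partition.
#' @param seed integer seed.
#' @param nRestarts GP fit restarts per fold.
#' @return a \linkS4class{CVResult}.
#' @export
inverseCrossValidate <- function(X, y, nFolds = 10L, nRepeats = 5L,
                                 seed = 1L, nRestarts = 3L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("X and y must align")
  if (n < nFolds) stop("need at least nFolds samples")
  recs <- vector("list", nRepeats * nFolds)
  ri <- 0L
  for (r in seq_len(nRepeats)) {
    folds <- foldPartition(n, nFolds, seed + r - 1L)
    for (f in seq_len(nFolds)) {
      trainIdx <- folds[[f]]
      testIdx <- setdiff(seq_len(n), trainIdx)
      model <- gpFit(X[trainIdx, , drop = FALSE], y[trainIdx],
                     nRestarts = nRestarts,
                     seed = seed + 1000L * r + f)
      pred <- gpPredict(model, X[testIdx, , drop = FALSE])
      ri <- ri + 1L
      recs[[ri]] <- data.frame(repeat_idx = r, fold = f,
                               sample = testIdx, prediction = pred$mean,
                               truth = y[testIdx])
    }
  }
  records <- do.call(rbind, recs)
  err <- records$prediction - records$truth
  foldKey <- interaction(records$repeat_idx, records$fold, drop = TRUE)
  foldRMS <- aggregate(err^2, list(key = foldKey), mean)
  foldRMS <- data.frame(
    repeat_idx = as.integer(sub("\\..*$", "", as.character(foldRMS$key))),
    fold = as.integer(sub("^.*\\.", "", as.character(foldRMS$key))),
    rms = sqrt(foldRMS$x))
  new("CVResult", records = records,
      pooledRMS = sqrt(mean(err^2)), foldRMS = foldRMS,
      meanFoldRMS = mean(foldRMS$rms), nFolds = as.integer(nFolds),
      nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

#' Write the per-sample CV records as CSV
#'
#' @param result a \linkS4class{CVResult}.
#' @param path file path.
#' @export
writeCVRecords <- function(result, path) {
  write.csv(result@records, path, row.names = FALSE)
  invisible(path)
}
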