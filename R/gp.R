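#' @include AllClasses.R
NULL

#' Construct ARD hyperparameters
#'
#' @param signalVariance signal variance, squared target units.
#' @param lengthScales per-dimension length-scales.
#' @param noiseVariance observation-noise variance.
#' @return a \linkS4class{GPHyperparams}.
#' @export
gpHyperparams <- function(signalVariance, lengthScales, noiseVariance) {
  new("GPHyperparams", signalVariance = signalVariance,
      lengthScales = lengthScales, noiseVariance = noiseVariance)
}

#' Squared-exponential ARD kernel
#'
#' \deqn{K_{ij} = \sigma_f^2 \exp(-\tfrac12 \sum_d (x_{1,i,d} -
#' x_{2,j,d})^2 / \ell_d^2)}
#'
#' @param X1,X2 feature matrices (rows are samples) with matching
#'   dimensionality.
#' @param hp a \linkS4class{GPHyperparams} with one length-scale per
#'   feature dimension.
#' @return the \code{nrow(X1)} x \code{nrow(X2)} covariance matrix.
#' @export
ardKernel <- function(X1, X2, hp) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("feature dimensionality mismatch")
  if (length(hp@lengthScales) != ncol(X1)) {
    stop("one length-scale per feature dimension required")
  }
  A <- sweep(X1, 2, hp@lengthScales, "/")
  B <- sweep(X2, 2, hp@lengthScales, "/")
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  hp@signalVariance * exp(-0.5 * pmax(D2, 0))
}

# triangular solve of (L L^T) alpha = y with iterative refinement; the
# refinement steps matter when sn2 is far below the kernel's conditioning
solveChol <- function(L, y, refine = 2L) {
  alpha <- backsolve(t(L), forwardsolve(L, y))
  for (i in seq_len(refine)) {
    r <- y - as.numeric(L %*% crossprod(L, alpha))
    alpha <- alpha + backsolve(t(L), forwardsolve(L, r))
  }
  alpha
}

# Cholesky of K + sn2 I with a jitter ladder; stops at 1e-6 * trace / n
cholWithJitter <- function(K, sn2) {
  n <- nrow(K)
  Ky <- K + diag(sn2, n)
  jmax <- 1e-6 * sum(diag(Ky)) / n
  jitter <- 0
  repeat {
    L <- tryCatch(t(chol(Ky + diag(jitter, n))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jitter))
    jitter <- if (jitter == 0) 1e-10 else jitter * 100
    if (jitter > jmax) stop("ill-conditioned kernel: factorization failed")
  }
}

#' Log marginal likelihood of a GP and its gradient
#'
#' Computes \deqn{-\tfrac12 y^\top (K+\sigma_n^2 I)^{-1} y - \tfrac12
#' \log\det(K+\sigma_n^2 I) - \tfrac{n}{2}\log 2\pi} through the
#' triangular factorization, together with the analytic gradient with
#' respect to the log-hyperparameters (log signal variance, log
#' length-scales, log noise variance).
#'
#' @param X n x d feature matrix.
#' @param y length-n targets (assumed centered by the caller).
#' @param hp a \linkS4class{GPHyperparams}.
#' @return list with \code{value}, \code{gradient} (length d + 2, order:
#'   log signal variance, log length-scales, log noise variance), and the
#'   factorization (\code{L}, \code{alpha}).
#' @export
logMarginalLikelihood <- function(X, y, hp) {
  X <- as.matrix(X)
  n <- nrow(X)
  Kf <- ardKernel(X, X, hp)
  fac <- cholWithJitter(Kf, hp@noiseVariance)
  L <- fac$L
  alpha <- backsolve(t(L), forwardsolve(L, y))
  value <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  Kinv <- chol2inv(t(L))
  A <- tcrossprod(alpha) - Kinv
  d <- ncol(X)
  grad <- numeric(d + 2)
  grad[1] <- 0.5 * sum(A * Kf)
  for (j in seq_len(d)) {
    D2j <- outer(X[, j], X[, j], "-")^2 / hp@lengthScales[j]^2
    grad[1 + j] <- 0.5 * sum(A * (Kf * D2j))
  }
  grad[d + 2] <- 0.5 * hp@noiseVariance * sum(diag(A))
  names(grad) <- c("log_sf2", paste0("log_l", seq_len(d)), "log_sn2")
  list(value = value, gradient = grad, L = L, alpha = alpha)
}

#' Fit a GP regression model
#'
#' Standardizes the features to zero mean and unit SD and centers the
#' targets (both on the supplied data only), then maximizes the log
#' marginal likelihood over the log-hyperparameters by gradient-based
#' ascent (L-BFGS with the analytic gradient) from a data-driven start
#' plus seeded random restarts. Pass \code{hp} to skip optimization and
#' condition on fixed hyperparameters.
#'
#' @param X n x d feature matrix.
#' @param y length-n targets, mm.
#' @param hp optional fixed \linkS4class{GPHyperparams} (standardized-
#'   feature units).
#' @param nRestarts random restarts in addition to the default start.
#' @param seed integer seed for the restarts.
#' @param standardize standardize features internally (default TRUE; when
#'   FALSE the features are used as supplied).
#' @param maxit optimizer iteration cap per start.
#' @return a \linkS4class{GPModel}.
#' @export
gpFit <- function(X, y, hp = NULL, nRestarts = 3L, seed = 1L,
                  standardize = TRUE, maxit = 200L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("need at least 2 training samples")
  if (length(y) != n) stop("X and y must align")
  if (standardize) {
    xc <- colMeans(X)
    xs <- apply(X, 2, sd)
    xs[!is.finite(xs) | xs < 1e-12] <- 1
  } else {
    xc <- rep(0, d); xs <- rep(1, d)
  }
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yc <- mean(y)
  ys <- y - yc
  vy <- max(var(ys), 1e-12)

  if (!is.null(hp)) {
    fac <- cholWithJitter(ardKernel(Xs, Xs, hp), hp@noiseVariance)
    alpha <- solveChol(fac$L, ys)
    obj <- logMarginalLikelihood(Xs, ys, hp)$value
    return(new("GPModel", X = Xs, y = ys, xCenter = xc, xScale = xs,
               yCenter = yc, hyper = hp, L = fac$L, alpha = alpha,
               objective = obj, trace = obj))
  }

  evalEnv <- new.env()
  evalEnv$best <- -Inf
  evalEnv$trace <- numeric(0)
  fn <- function(p) {
    hpp <- gpHyperparams(exp(p[1]), exp(p[2:(d + 1)]), exp(p[d + 2]))
    v <- tryCatch(logMarginalLikelihood(Xs, ys, hpp)$value,
                  error = function(e) NA_real_)
    if (!is.finite(v)) return(-1e10)
    if (v > evalEnv$best) {
      evalEnv$best <- v
      evalEnv$trace <- c(evalEnv$trace, v)
    }
    v
  }
  gr <- function(p) {
    hpp <- gpHyperparams(exp(p[1]), exp(p[2:(d + 1)]), exp(p[d + 2]))
    g <- tryCatch(logMarginalLikelihood(Xs, ys, hpp)$gradient,
                  error = function(e) rep(0, d + 2))
    if (any(!is.finite(g))) g <- rep(0, d + 2)
    g
  }

  starts <- withSeed(as.integer(seed), {
    s0 <- c(log(vy), rep(0, d), log(0.1 * vy + 1e-6))
    ss <- list(s0)
    for (r in seq_len(nRestarts)) {
      ss[[r + 1]] <- c(log(vy) + runif(1, -1, 1),
                       runif(d, -1, 1.5),
                       log(vy) + runif(1, -7, -1))
    }
    ss
  })

  bestPar <- NULL
  bestVal <- -Inf
  nFail <- 0L
  for (s in starts) {
    # bounded search: signal variance capped at 1e3 x the target variance
    # and length-scales at e^3 standardized units, cutting the degenerate
    # ridge (sf2, l -> infinity jointly) where the kernel loses rank
    res <- tryCatch(
      optim(s, fn, gr, method = "L-BFGS-B",
            lower = c(rep(-15, d + 1), -26),
            upper = c(log(1e3 * vy), rep(3, d), 15),
            control = list(fnscale = -1, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) { nFail <- nFail + 1L; next }
    if (res$value > bestVal) {
      bestVal <- res$value
      bestPar <- res$par
    }
  }
  if (is.null(bestPar)) {
    stop(sprintf("GP fit failed: all %d starts errored", nFail))
  }
  hpBest <- gpHyperparams(exp(bestPar[1]), exp(bestPar[2:(d + 1)]),
                          exp(bestPar[d + 2]))
  fac <- cholWithJitter(ardKernel(Xs, Xs, hpBest), hpBest@noiseVariance)
  alpha <- solveChol(fac$L, ys)
  new("GPModel", X = Xs, y = ys, xCenter = xc, xScale = xs, yCenter = yc,
      hyper = hpBest, L = fac$L, alpha = alpha, objective = bestVal,
      trace = evalEnv$trace)
}

#' GP predictive mean and variance
#'
#' Standard Gaussian-process conditionals, de-standardized back to mm: the
#' predictive mean of the latent function plus the training-target mean,
#' and the latent predictive variance (without observation noise).
#' Variances that come out numerically negative beyond -1e-9 trigger a
#' warning; small negatives are clipped to 0.
#'
#' @param model a \linkS4class{GPModel}.
#' @param Xstar m x d query features (original, unstandardized units).
#' @return data.frame with columns \code{mean} (mm) and \code{variance}
#'   (mm^2).
#' @export
gpPredict <- function(model, Xstar) {
  Xstar <- as.matrix(Xstar)
  if (ncol(Xstar) != ncol(model@X)) stop("feature dimensionality mismatch")
  Xs <- sweep(sweep(Xstar, 2, model@xCenter), 2, model@xScale, "/")
  Ks <- ardKernel(Xs, model@X, model@hyper)
  mu <- as.numeric(Ks %*% model@alpha) + model@yCenter
  v <- forwardsolve(model@L, t(Ks))
  varLatent <- model@hyper@signalVariance - colSums(v^2)
  if (any(varLatent < -1e-9)) {
    warning("predictive variance numerically negative; clipped to 0")
  }
  data.frame(mean = mu, variance = pmax(varLatent, 0))
}

#' Serialize a GP model as JSON
#'
#' Writes the fitted hyperparameters, the standardization constants, the
#' training-set shape and an MD5 hash of the training data (reference for
#' reproducibility checks).
#'
#' @param model a \linkS4class{GPModel}.
#' @param path file path.
#' @export
writeGPModelJSON <- function(model, path) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(c(as.numeric(model@X), model@y), tf)
  obj <- list(
    hyperparams = list(signal_variance = model@hyper@signalVariance,
                       length_scales = model@hyper@lengthScales,
                       noise_variance = model@hyper@noiseVariance),
    standardization = list(x_center = model@xCenter, x_scale = model@xScale,
                           y_center = model@yCenter),
    n_train = nrow(model@X), n_features = ncol(model@X),
    log_marginal_likelihood = model@objective,
    training_data_md5 = unname(tools::md5sum(tf)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
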