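# shared fixtures and independent oracles, built in code and memoised so
# expensive objects are computed once per test run

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

subject1Config <- function() {
  memo("subject1cfg", readSubjectConfig(subjectConfigPath("subject1")))
}

# flat phantom: no dome, no relief, constant 5 mm thickness
flatPhantom <- function(seed = 3L) {
  generatePhantom(thicknessRange = c(5, 5), curvatureRadius = Inf,
                  roughnessAmp = 0, seed = seed)
}

# noiseless flat-phantom scan on a small grid (shared across files)
noiselessFlatScan <- function() {
  memo("flatscan", {
    cfg <- scanConfig(gridRows = 8L, gridCols = 8L, noiseCV = 0,
                      backgroundSD = 0, snrThreshold = 0, rngSeed = 11L)
    generateNirScan(flatPhantom(), cfg, triNoiseSD = 0, seed = 11L)
  })
}

# zero-noise full pipeline run (shared by invariants and acceptance)
zeroNoisePipeline <- function() {
  memo("zeronoise", {
    zn <- list(noise = list(feature_cv = 0, thickness_sd_mm = 0,
                            marker_sd_mm = 0, tri_pixel_sd_px = 0,
                            background_sd = 0, background_sd_scan = 0),
               mri = list(out_plane_pitch_mm = 0.15),
               gp = list(repeats = 1))
    runPipeline(subjectConfigPath("subject1"), seed = 5, overrides = zn)
  })
}

## independent oracles -----------------------------------------------------

# naive per-pixel double loop for annulus means
annulusOracle <- function(image, centroid, radii, pixelPitch,
                          normalize = TRUE) {
  edges <- c(0, radii)
  sums <- numeric(length(radii))
  counts <- integer(length(radii))
  tot <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      d <- pixelPitch * sqrt((i - 1 - centroid[1])^2 +
                             (j - 1 - centroid[2])^2)
      if (d < radii[length(radii)]) tot <- tot + image[i, j]
      for (k in seq_along(radii)) {
        if (d >= edges[k] && d < edges[k + 1]) {
          sums[k] <- sums[k] + image[i, j]
          counts[k] <- counts[k] + 1L
        }
      }
    }
  }
  m <- sums / counts
  if (normalize) m / tot else m
}

# scalar double-loop ARD kernel
ardKernelOracle <- function(X1, X2, sf2, ls) {
  K <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1))) {
    for (j in seq_len(nrow(X2))) {
      s <- 0
      for (d in seq_len(ncol(X1))) {
        s <- s + (X1[i, d] - X2[j, d])^2 / ls[d]^2
      }
      K[i, j] <- sf2 * exp(-0.5 * s)
    }
  }
  K
}

# GP prediction through an explicit dense inverse
gpPredictOracle <- function(X, y, Xstar, hp) {
  Ky <- ardKernelOracle(X, X, hp@signalVariance, hp@lengthScales) +
    diag(hp@noiseVariance, nrow(X))
  Ks <- ardKernelOracle(Xstar, X, hp@signalVariance, hp@lengthScales)
  Kinv <- solve(Ky)
  mu <- as.numeric(Ks %*% Kinv %*% y)
  v <- hp@signalVariance - diag(Ks %*% Kinv %*% t(Ks))
  list(mean = mu, variance = v)
}

# closed-form closest point of two skew rays via the 2x2 normal equations
rayMidpointOracle <- function(o1, d1, o2, d2) {
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  A <- matrix(c(sum(d1 * d1), -sum(d1 * d2),
                sum(d1 * d2), -sum(d2 * d2)), 2, 2, byrow = TRUE)
  b <- c(sum((o2 - o1) * d1), sum((o2 - o1) * d2))
  t12 <- solve(A, b)
  p1 <- o1 + t12[1] * d1
  p2 <- o2 + t12[2] * d2
  list(point = (p1 + p2) / 2, residual = sqrt(sum((p1 - p2)^2)))
}

# brute-force rigid fit: dense Euler-angle grid (coarse then refined),
# translation optimal in closed form for each candidate rotation
rigidFitGridOracle <- function(src, dst, span = 15, step = 1.5) {
  eulerR <- function(a, b, c) {
    rotationAboutAxis(c(0, 0, 1), c) %*%
      rotationAboutAxis(c(0, 1, 0), b) %*%
      rotationAboutAxis(c(1, 0, 0), a)
  }
  sc <- colMeans(src); dc <- colMeans(dst)
  S <- sweep(src, 2, sc); D <- sweep(dst, 2, dc)
  best <- Inf
  evalGrid <- function(center, span, step) {
    gr <- seq(-span, span, by = step) * pi / 180
    for (a in center[1] + gr) for (b in center[2] + gr) {
      for (c in center[3] + gr) {
        R <- eulerR(a, b, c)
        rms <- sqrt(mean(rowSums((S %*% t(R) - D)^2)))
        if (rms < best) {
          best <<- rms
          bestAng <<- c(a, b, c)
        }
      }
    }
  }
  bestAng <- c(0, 0, 0)
  evalGrid(c(0, 0, 0), span, step)
  evalGrid(bestAng, step * 1.2, step / 10)
  best
}
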