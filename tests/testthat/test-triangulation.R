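test_that("galvo rays are unit-norm and reproduce the grid geometry", {
  calib <- galvoCalibrationForGrid()
  for (idx in list(c(1, 1), c(16, 16), c(32, 32), c(7, 29))) {
    ray <- galvoRay(calib, idx[1], idx[2])
    expect_equal(sqrt(sum(ray$direction^2)), 1, tolerance = 1e-9)
  }
  expect_error(galvoRay(calib, 0, 5), "out of")
  expect_error(galvoRay(calib, 5, 33), "out of")

  # boresight: with an even grid the two central columns straddle the axis
  # symmetrically; a 33-column grid has an exact central boresight ray
  c33 <- galvoCalibrationForGrid(33L, 33L)
  expect_equal(galvoRay(c33, 17, 17)$direction, c(0, 0, -1),
               tolerance = 1e-12)

  # adjacent columns land ~1.5 mm apart on the target plane at z = 0
  r1 <- galvoRay(calib, 16, 16)
  r2 <- galvoRay(calib, 16, 17)
  t1 <- -r1$origin[3] / r1$direction[3]
  t2 <- -r2$origin[3] / r2$direction[3]
  p1 <- r1$origin + t1 * r1$direction
  p2 <- r2$origin + t2 * r2$direction
  expect_equal(sqrt(sum((p1 - p2)^2)), 1.5, tolerance = 0.05)
})

test_that("triangulation is exact for noiseless projections", {
  cam <- defaultTriangulationCamera()
  calib <- galvoCalibrationForGrid()
  set.seed(5)
  for (i in 1:25) {
    ray <- galvoRay(calib, sample(32, 1), sample(32, 1))
    t <- runif(1, 450, 520)
    p <- ray$origin + t * ray$direction
    px <- projectPoint(cam, p)
    tri <- triangulatePoint(ray, cam, px)
    expect_lt(sqrt(sum((tri$point - p)^2)), 1e-9)
    expect_lt(tri$residual, 1e-9)
  }
})

test_that("triangulation is exact for 100 random camera geometries", {
  set.seed(17)
  for (i in 1:100) {
    pos <- c(runif(1, -250, 250), runif(1, -250, 250), runif(1, 350, 650))
    cam <- cameraLookingAt(pos, lookAt = runif(3, -20, 20),
                           focalPx = runif(1, 1000, 3000))
    ray <- list(origin = c(0, 0, 500),
                direction = c(runif(2, -0.2, 0.2), -1))
    ray$direction <- ray$direction / sqrt(sum(ray$direction^2))
    p <- ray$origin + runif(1, 400, 600) * ray$direction
    tri <- tryCatch(triangulatePoint(ray, cam, projectPoint(cam, p)),
                    error = function(e) NULL)
    if (is.null(tri)) next    # near-parallel draw, legitimately rejected
    expect_lt(sqrt(sum((tri$point - p)^2)), 1e-9)
  }
})

test_that("the midpoint solution matches the hand-built normal-equation oracle", {
  cases <- list(
    list(o1 = c(0, 0, 0), d1 = c(0, 0, 1), o2 = c(10, 0, 0), d2 = c(0, 1, 0)),
    list(o1 = c(1, 2, 3), d1 = c(1, 1, 0), o2 = c(-4, 0, 2), d2 = c(0, 1, 1)),
    list(o1 = c(5, -3, 1), d1 = c(2, 0, -1), o2 = c(0, 4, -2), d2 = c(-1, 1, 3)))
  for (cs in cases) {
    got <- nirtomo:::rayMidpoint(list(origin = cs$o1, direction = cs$d1),
                                 list(origin = cs$o2, direction = cs$d2))
    want <- rayMidpointOracle(cs$o1, cs$d1, cs$o2, cs$d2)
    expect_equal(got$point, want$point, tolerance = 1e-10)
    expect_equal(got$residual, want$residual, tolerance = 1e-10)
  }
  expect_error(nirtomo:::rayMidpoint(
    list(origin = c(0, 0, 0), direction = c(0, 0, 1)),
    list(origin = c(1, 0, 0), direction = c(0, 0, 1))), "degenerate")
})

test_that("pixel perturbations stay within the sensitivity bound", {
  cam <- defaultTriangulationCamera()
  calib <- galvoCalibrationForGrid()
  ray <- galvoRay(calib, 16, 16)
  p <- ray$origin + 500 * ray$direction
  px <- projectPoint(cam, p)
  # numeric sensitivity of the default geometry, mm per px
  sens <- max(vapply(list(c(0.5, 0), c(0, 0.5), c(-0.5, 0), c(0, -0.5)),
                     function(dpx) {
    sqrt(sum((triangulatePoint(ray, cam, px + dpx)$point - p)^2)) /
      sqrt(sum(dpx^2))
  }, numeric(1)))
  expect_lt(0.5 * sens, 0.5)   # < 0.5 mm error for a 0.5 px perturbation
})

test_that("reconstruction recovers flat and domed surfaces", {
  scan <- noiselessFlatScan()
  cloud <- reconstructScan(scan)
  expect_lt(max(cloud@residuals), 1e-6)
  nrm <- cloudNormals(cloud)
  ang <- acos(pmin(1, abs(nrm[, 3]))) * 180 / pi
  expect_lt(max(ang), 0.1)     # flat phantom: all normals along +z

  dome <- generatePhantom(seed = 12)
  cfg <- scanConfig(gridRows = 12L, gridCols = 12L, noiseCV = 0,
                    backgroundSD = 0, snrThreshold = 0)
  dscan <- generateNirScan(dome, cfg, triNoiseSD = 0, seed = 12)
  dcloud <- reconstructScan(dscan)
  pts <- cloudPoints(dcloud)
  expect_lt(sqrt(mean((pts[, 3] -
                       surfaceHeight(dome, pts[, 1], pts[, 2]))^2)), 1e-3)
})

test_that("reconstruction error grows monotonically with pixel noise", {
  dome <- generatePhantom(seed = 13)
  cfg <- scanConfig(gridRows = 10L, gridCols = 10L, noiseCV = 0,
                    backgroundSD = 0, snrThreshold = 0)
  rmsAt <- vapply(c(0, 0.1, 0.3, 0.5), function(s) {
    scan <- generateNirScan(dome, cfg, triNoiseSD = s, seed = 13)
    cloud <- reconstructScan(scan)
    pts <- cloudPoints(cloud)
    tru <- cbind(scan@meta$x, scan@meta$y, scan@meta$z)[scan@meta$valid, ]
    sqrt(mean(rowSums((pts - tru)^2)))
  }, numeric(1))
  expect_true(all(diff(rmsAt) > 0))
})

test_that("plane-fit normals are density-independent on a plane", {
  set.seed(3)
  for (n in c(30, 120, 500)) {
    pts <- cbind(runif(n, -10, 10), runif(n, -10, 10), 0)
    nrm <- nirtomo:::estimateNormals(pts, k = 8L, toward = c(0, 0, 100))
    expect_lt(max(acos(pmin(1, nrm[, 3])) * 180 / pi), 1e-6)
  }
})

test_that("point clouds survive a PLY round-trip", {
  scan <- noiselessFlatScan()
  cloud <- reconstructScan(scan)
  path <- tempfile(fileext = ".ply")
  writePLY(cloud, path)
  back <- readPLY(path)
  expect_equal(as.matrix(back[, c("x", "y", "z")]), cloudPoints(cloud),
               tolerance = 1e-6, ignore_attr = TRUE)

  few <- scan
  few@meta$valid[-(1:2)] <- FALSE
  expect_error(reconstructScan(few), "cannot reconstruct")
})
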