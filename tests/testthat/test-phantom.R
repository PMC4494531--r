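test_that("phantom generation is deterministic and respects the range", {
  p1 <- generatePhantom(seed = 1)
  p2 <- generatePhantom(seed = 1)
  expect_identical(p1@surface, p2@surface)
  expect_identical(p1@thicknessField, p2@thicknessField)
  expect_identical(p1@markers, p2@markers)
  expect_identical(rotation(p1@mriTransform), rotation(p2@mriTransform))

  # dense evaluation of the generated field stays inside [2, 14] and
  # comes within 0.5 mm of both bounds
  set.seed(9)
  x <- runif(1e4, -24, 24); y <- runif(1e4, -16, 16)
  d <- thicknessAt(p1, x, y)
  expect_true(all(d >= 2 & d <= 14))
  expect_lt(min(d) - 2, 0.5)
  expect_lt(14 - max(d), 0.5)
})

test_that("a degenerate range yields a constant thickness field", {
  p <- generatePhantom(thicknessRange = c(5, 5), seed = 4)
  expect_equal(thicknessAt(p, c(-10, 0, 13), c(2, 0, -9)), rep(5, 3))
})

test_that("invalid thickness ranges are rejected with a message", {
  expect_error(generatePhantom(thicknessRange = c(6, 4), seed = 1),
               "invalid")
  expect_error(generatePhantom(thicknessRange = c(-1, 5), seed = 1),
               "invalid")
  expect_error(generatePhantom(thicknessRange = c(1, 25), seed = 1),
               "within")
})

test_that("surface normals agree with finite differences of the height", {
  p <- generatePhantom(seed = 6)
  h <- 1e-5
  for (pt in list(c(0, 0), c(8, -5), c(-15, 10))) {
    gx <- (surfaceHeight(p, pt[1] + h, pt[2]) -
           surfaceHeight(p, pt[1] - h, pt[2])) / (2 * h)
    gy <- (surfaceHeight(p, pt[1], pt[2] + h) -
           surfaceHeight(p, pt[1], pt[2] - h)) / (2 * h)
    n <- c(-gx, -gy, 1); n <- n / sqrt(sum(n^2))
    expect_equal(as.numeric(surfaceNormalAt(p, pt[1], pt[2])), n,
                 tolerance = 1e-6)
  }
})

test_that("the ground-truth modality offset respects its bounds", {
  for (s in 1:10) {
    p <- generatePhantom(seed = s)
    expect_lte(rotationAngle(p@mriTransform), 20 * pi / 180 + 1e-12)
    expect_true(all(abs(translation(p@mriTransform)) <= 50))
  }
})

test_that("MRI sampling follows the grid arithmetic and noise model", {
  p <- generatePhantom(patchSize = c(30, 30), seed = 2)
  mri <- generateMriDataset(p, 0.15, 1.0, seed = 3)
  expect_equal(nrow(cloudPoints(mri)),
               (floor(30 / 0.15) + 1) * (floor(30 / 1.0) + 1))

  # zero noise + identity modality offset: points lie on the surface
  pId <- p
  pId@mriTransform <- rigidTransform()
  mri0 <- generateMriDataset(pId, 0.5, 1.0, seed = 3)
  pts <- cloudPoints(mri0)
  expect_lt(max(abs(pts[, 3] - surfaceHeight(p, pts[, 1], pts[, 2]))),
            1e-9)
  expect_equal(thicknessValues(mri0),
               thicknessAt(p, pts[, 1], pts[, 2]), tolerance = 1e-12)

  # moment check on the segmentation noise
  mriN <- generateMriDataset(pId, 0.25, 0.35, thicknessNoiseSD = 0.1,
                             seed = 4)
  resid <- thicknessValues(mriN) -
    thicknessAt(p, cloudPoints(mriN)[, 1], cloudPoints(mriN)[, 2])
  expect_gt(length(resid), 1e4)
  expect_gt(sd(resid), 0.09)
  expect_lt(sd(resid), 0.11)
})
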