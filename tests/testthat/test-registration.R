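mk <- function(p, labels = paste0("M", seq_len(nrow(p)))) {
  data.frame(label = labels, x = p[, 1], y = p[, 2], z = p[, 3],
             stringsAsFactors = FALSE)
}

test_that("landmark alignment recovers exact transforms", {
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(3, 3, 6))
  # identity
  tr <- landmarkAlign(mk(src), mk(src))
  expect_lt(max(abs(rotation(tr) - diag(3))), 1e-9)
  expect_lt(sqrt(sum(translation(tr)^2)), 1e-9)
  # known rotation 25 deg about z plus translation (3, -2, 7)
  R <- rotationAboutAxis(c(0, 0, 1), 25 * pi / 180)
  t0 <- c(3, -2, 7)
  dst <- sweep(src %*% t(R), 2, t0, "+")
  tr2 <- landmarkAlign(mk(src), mk(dst))
  expect_lt(max(abs(rotation(tr2) - R)), 1e-9)
  expect_lt(max(abs(translation(tr2) - t0)), 1e-9)
})

test_that("landmark alignment is invariant to marker permutations", {
  set.seed(8)
  src <- matrix(runif(12, -10, 10), 4, 3)
  dst <- applyTransform(randomRigidTransform(), src) +
    matrix(rnorm(12, 0, 0.2), 4, 3)
  a <- landmarkAlign(mk(src), mk(dst))
  perm <- c(3, 1, 4, 2)
  b <- landmarkAlign(mk(src[perm, ], labels = paste0("M", perm)), mk(dst))
  expect_equal(rotation(a), rotation(b), tolerance = 1e-12)
  expect_equal(translation(a), translation(b), tolerance = 1e-12)
})

test_that("degenerate marker sets are rejected", {
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(landmarkAlign(mk(line), mk(line)), "collinear")
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(landmarkAlign(mk(two), mk(two)), "3 shared")
})

test_that("the noisy 4-marker fit attains the grid-search minimum", {
  set.seed(14)
  src <- rbind(c(-8, -6, 0), c(8, -6, 1), c(8, 6, 0), c(-8, 6, 2))
  dst <- src + matrix(rnorm(12, 0, 0.5), 4, 3)
  tr <- landmarkAlign(mk(src), mk(dst))
  rmsKabsch <- sqrt(mean(rowSums((applyTransform(tr, src) - dst)^2)))
  rmsGrid <- rigidFitGridOracle(src, dst)
  expect_lte(rmsKabsch, rmsGrid + 1e-3)
})

test_that("ICP converges instantly when the source is a target subsample", {
  set.seed(2)
  tgt <- cbind(runif(400, -20, 20), runif(400, -20, 20), rnorm(400, 0, 2))
  src <- tgt[sample(400, 120), ]
  reg <- icpRefine(src, tgt)
  expect_lt(reg@rms, 1e-6)
  expect_lte(reg@iterations, 2L)
  expect_true(reg@converged)
})

test_that("ICP recovers a known small perturbation to 0.05 deg / 0.05 mm", {
  # unstructured sampling: regular grids can lock nearest-neighbour
  # correspondences onto a lattice-shifted local minimum
  set.seed(22)
  ph <- generatePhantom(seed = 21, roughnessAmp = 2)
  x <- runif(2500, -22, 22); y <- runif(2500, -14, 14)
  tgt <- cbind(x, y, surfaceHeight(ph, x, y))
  pert <- rigidTransform(rotationAboutAxis(c(0.3, 1, 0.5), 3 * pi / 180),
                         c(1.2, -1, 1.1))     # 3 deg, 2 mm
  src <- applyTransform(invertTransform(pert), tgt)
  reg <- icpRefine(src, tgt, params = new("ICPParams", rmsChangeTol = 1e-6,
                                          maxIterations = 200L))
  err <- composeTransforms(invertTransform(pert), reg@transform)
  expect_lt(rotationAngle(err) * 180 / pi, 0.05)
  expect_lt(sqrt(sum(translation(err)^2)), 0.05)
})

test_that("noiseless synthetic registration recovers the modality offset exactly", {
  ph <- generatePhantom(seed = 23)
  g <- expand.grid(x = seq(-22, 22, by = 0.8), y = seq(-14, 14, by = 0.8))
  src <- cbind(g$x, g$y, surfaceHeight(ph, g$x, g$y))
  tgt <- applyTransform(ph@mriTransform, src)
  init <- landmarkAlign(ph@markers,
                        mk(applyTransform(ph@mriTransform,
                                          as.matrix(ph@markers[, 2:4]))))
  reg <- icpRefine(src, tgt, init)
  err <- composeTransforms(invertTransform(ph@mriTransform), reg@transform)
  expect_lt(rotationAngle(err), 1e-6)
  expect_lt(sqrt(sum(translation(err)^2)), 1e-6)
})

test_that("the ICP rms trace never increases across an update", {
  set.seed(31)
  ph <- generatePhantom(seed = 31)
  g <- expand.grid(x = seq(-22, 22, length.out = 32),
                   y = seq(-14, 14, length.out = 32))
  pts <- cbind(g$x, g$y, surfaceHeight(ph, g$x, g$y))
  tgt <- applyTransform(ph@mriTransform, pts) +
    matrix(rnorm(length(pts), 0, 0.3), nrow(pts), 3)
  src <- pts + matrix(rnorm(length(pts), 0, 0.3), nrow(pts), 3)
  mks <- applyTransform(ph@mriTransform, as.matrix(ph@markers[, 2:4])) +
    matrix(rnorm(12, 0, 0.5), 4, 3)
  init <- landmarkAlign(ph@markers, mk(mks))
  reg <- icpRefine(src, tgt, init)
  # closed-form update is optimal on its own correspondences
  expect_true(all(reg@trace <= reg@preTrace + 1e-12))
  # and the overall trace is non-increasing
  expect_true(all(diff(reg@trace) <= 1e-9))
})

test_that("empty correspondence sets signal divergence", {
  src <- cbind(runif(20), runif(20), runif(20))
  tgt <- src + 100    # far beyond the correspondence cap
  expect_error(icpRefine(src, tgt), "divergence")
})

test_that("thickness labels transfer by inverse-distance weighting", {
  mri <- new("MRIThicknessMap",
             points = rbind(c(1, 0, 0), c(0, 0.2, 0),
                            c(0, -0.2, 0), c(5, 5, 5)),
             thickness = c(9, 4, 6, 8),
             markers = data.frame(label = "M1", x = 0, y = 0, z = 0))
  # coincident with a single MRI point -> exactly that thickness
  lab <- transferThicknessLabels(rbind(c(1, 0, 0)), mri, radius = 0.3)
  expect_identical(as.numeric(lab), 9)
  # two equidistant neighbours with 4 and 6 mm -> 5 mm
  lab2 <- transferThicknessLabels(rbind(c(0, 0, 0)), mri, radius = 0.25)
  expect_equal(as.numeric(lab2), 5)
  # no neighbour in radius -> unlabeled
  lab3 <- transferThicknessLabels(rbind(c(-3, -3, -3)), mri, radius = 0.5)
  expect_true(is.na(lab3))
  expect_identical(attr(lab3, "count"), 0L)
  # the gate refuses to label misaligned data
  expect_error(transferThicknessLabels(rbind(c(0, 0, 0)), mri,
                                       registrationRMS = 2, gate = 1),
               "gate")
})

test_that("zero-noise label transfer reproduces the ground truth", {
  ph <- generatePhantom(seed = 33)
  phId <- ph
  phId@mriTransform <- rigidTransform()
  mri <- generateMriDataset(phId, 0.1, 0.1, seed = 2)
  g <- expand.grid(x = seq(-20, 20, by = 1.7), y = seq(-12, 12, by = 1.3))
  cloud <- cbind(g$x, g$y, surfaceHeight(ph, g$x, g$y))
  # small radius relative to the field curvature: IDW smoothing bias is
  # ~f'' r^2 / 4, below 1e-3 mm at r = 0.1 mm
  lab <- transferThicknessLabels(cloud, mri, radius = 0.1)
  tru <- thicknessAt(ph, g$x, g$y)
  expect_lt(max(abs(lab - tru)), 1e-3)
  # at the default radius the error is bounded by the smoothing scale
  lab5 <- transferThicknessLabels(cloud, mri, radius = 0.5)
  expect_lt(max(abs(lab5 - tru)), 0.05)
})
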