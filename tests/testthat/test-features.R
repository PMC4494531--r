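test_that("centroids follow intensity weighting after background subtraction", {
  img <- matrix(0, 21, 21)
  img[11, 8] <- 5             # 0-based (10, 7)
  expect_equal(computeCentroid(img), c(10, 7))

  img2 <- matrix(0, 15, 15)
  img2[1, 1] <- 2; img2[1, 11] <- 2   # 0-based (0,0) and (0,10)
  expect_equal(computeCentroid(img2), c(0, 5))

  expect_error(computeCentroid(matrix(0, 9, 9)), "empty spot")
})

test_that("the centroid of a rendered noiseless spot hits the projected center", {
  img <- renderSpotImage(surrogateProfile(6), incidenceAngle = 12,
                         pixelPitch = 0.1, imageSize = 141L)
  cen <- computeCentroid(img)
  expect_lt(max(abs(cen - c(70, 70))), 0.05)
})

test_that("annulus features match the naive per-pixel oracle", {
  set.seed(21)
  img <- renderSpotImage(surrogateProfile(5), 0, 0.1, 141L,
                         noiseCV = 0.05, seed = 3)
  cen <- computeCentroid(img)
  spec <- annulusSpec()
  got <- extractAnnulusFeatures(img, cen, spec, 0.1)
  want <- annulusOracle(img, cen, spec$radii, 0.1, normalize = TRUE)
  expect_equal(got, want, tolerance = 1e-12)

  specRaw <- annulusSpec(normalization = "none")
  gotRaw <- extractAnnulusFeatures(img, cen, specRaw, 0.1)
  wantRaw <- annulusOracle(img, cen, spec$radii, 0.1, normalize = FALSE)
  expect_equal(gotRaw, wantRaw, tolerance = 1e-12)
})

test_that("uniform and truncated images give the expected ring structure", {
  u <- matrix(2.5, 141, 141)
  f <- extractAnnulusFeatures(u, c(70, 70), annulusSpec(normalization = "none"),
                              0.1)
  expect_equal(f, rep(2.5, 6))

  # image nonzero only inside the first ring boundary: outer rings exactly 0
  img <- matrix(0, 141, 141)
  rows <- matrix(0:140, 141, 141); cols <- t(rows)
  d <- 0.1 * sqrt((rows - 70)^2 + (cols - 70)^2)
  img[d < 0.65] <- 1
  f2 <- extractAnnulusFeatures(img, c(70, 70), annulusSpec(), 0.1)
  expect_true(all(f2[2:6] == 0))
  expect_gt(f2[1], 0)
})

test_that("features are translation-equivariant and scale-invariant", {
  img <- renderSpotImage(surrogateProfile(8), 0, 0.1, 101L,
                         noiseCV = 0.05, seed = 9)
  sp <- annulusSpec(radii = c(0.65, 1.3, 2.0, 3.0))
  base <- extractAnnulusFeatures(img, c(50, 50), sp, 0.1)

  shifted <- matrix(0, 101, 101)
  shifted[1:94, 6:101] <- img[8:101, 1:96]    # shift by (-7, +5) pixels
  expect_identical(extractAnnulusFeatures(shifted, c(43, 55), sp, 0.1),
                   base)

  expect_equal(extractAnnulusFeatures(img * 7, c(50, 50), sp, 0.1), base,
               tolerance = 1e-12)
})

test_that("incident angle follows the closed form", {
  expect_equal(computeIncidentAngle(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(computeIncidentAngle(c(0, 0, 1), c(1, 0, 0)), 90)
  expect_equal(computeIncidentAngle(c(0, 0, 1),
                                    c(0, sin(pi / 6), cos(pi / 6))), 30,
               tolerance = 1e-12)
  expect_error(computeIncidentAngle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("feature tables account for every spot and are deterministic", {
  scan <- noiselessFlatScan()
  tab <- assembleFeatureTable(scan, snrThreshold = 0)
  expect_equal(nrow(tab), 64L)
  expect_true(all(tab$valid))                      # noiseless, all hit
  expect_equal(sum(tab$valid) + sum(tab$reject_reason != ""), 64L)
  expect_equal(tab$thickness_mm[tab$valid],
               scan@meta$thickness[tab$valid])

  tab2 <- assembleFeatureTable(scan, snrThreshold = 0)
  expect_identical(tab, tab2)

  path <- tempfile(fileext = ".csv")
  writeFeatureCSV(tab, path)
  expect_identical(names(readFeatureCSV(path)), names(tab))
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(gsub('"', "", hdr),
                   c("row", "col", paste0("f", 1:6), "angle_deg",
                     "thickness_mm", "valid", "reject_reason"))
})
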