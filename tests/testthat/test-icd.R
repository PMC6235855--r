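test_that("ROI extraction respects physical size and bounds", {
  img <- genCCPattern(c(128, 128), 10, 24, seed = 1)
  roi <- extractROI(img, c(64, 64), 650)
  expect_identical(dim(pixels(roi)), c(65L, 65L))     # 650 um at 10 um/px
  expect_equal(pixelSize(roi), 10)
  full <- extractROI(img, c(64, 64), 1270)
  expect_identical(dim(pixels(full)), c(127L, 127L))
  expect_error(extractROI(img, c(2, 2), 650), "exceeds")
})

test_that("the radial spectrum localizes a pure sinusoid and handles edge cases", {
  n <- 65; px <- 10
  Y <- matrix(rep(1:n, n), n)
  sinus <- EnFaceImage(127 + 100 * sin(2 * pi * Y * px / 24), px)
  sp <- radialPowerSpectrum(sinus)
  expect_lt(abs(sp@freqPerUm[which.max(sp@power)] - 1 / 24), 1 / (n * px))
  expect_true(all(diff(sp@freqPerUm) > 0))
  expect_lte(max(sp@freqPerUm), 1 / (2 * px) + 1e-12)
  # constant ROI: all-zero power after mean subtraction
  expect_true(all(radialPowerSpectrum(EnFaceImage(matrix(9, n, n), px))@power == 0))
  # white noise: approximately flat profile
  set.seed(6)
  wn <- radialPowerSpectrum(EnFaceImage(matrix(runif(n * n) * 255, n, n), px))
  expect_lte(max(wn@power) / median(wn@power), 5)
  expect_error(radialPowerSpectrum(EnFaceImage(matrix(1, 40, 64), px)), "square")
})

test_that("generator-truth spacing is recovered within one bin at 65-px ROIs", {
  ests <- vapply(c(20, 24, 28, 32), function(icd) {
    img <- genCCPattern(c(256, 256), 10, icd, seed = 3)
    estimateICD(radialPowerSpectrum(extractROI(img, c(128, 128), 650)))$icdUm
  }, numeric(1))
  expect_true(all(abs(ests - c(20, 24, 28, 32)) <= 2))
  expect_true(all(diff(ests) > 0))   # macula-to-equator ordering preserved
})

test_that("no-cusp inputs raise the dedicated error", {
  flat <- radialPowerSpectrum(EnFaceImage(matrix(5, 65, 65), 10))
  expect_error(estimateICD(flat), "cusp")
  expect_error(estimateICD(flat, bandUm = c(60, 15)))
})

test_that("the estimate is rotation invariant and scale equivariant", {
  img <- genCCPattern(c(256, 256), 10, 24, seed = 2)
  roi <- extractROI(img, c(128, 128), 650)
  e0 <- estimateICD(radialPowerSpectrum(roi))$icdUm
  # 90 degrees: exact invariance
  r90 <- EnFaceImage(t(pixels(roi))[ncol(pixels(roi)):1, ], 10)
  expect_equal(estimateICD(radialPowerSpectrum(r90))$icdUm, e0)
  # 45 degrees: within one frequency bin
  rot <- pmax(EBImage::rotate(pixels(img), 45), 0)
  ctr <- round(dim(rot) / 2)
  e45 <- estimateICD(radialPowerSpectrum(
    extractROI(EnFaceImage(rot, 10), ctr, 650)))$icdUm
  expect_lte(abs(1 / e45 - 1 / e0), 1 / 650 + 1e-9)
  # resampling to 5 um/px recovers the same physical spacing
  up <- pmax(EBImage::resize(pixels(img), w = 512, h = 512), 0)
  e5 <- estimateICD(radialPowerSpectrum(
    extractROI(EnFaceImage(up, 5), c(256, 256), 650)))$icdUm
  expect_lte(abs(e5 - e0), 1)
})
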