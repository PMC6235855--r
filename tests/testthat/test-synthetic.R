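test_that("generators are deterministic under a fixed seed", {
  a <- genCCPattern(c(96, 96), 10, 24, seed = 4)
  b <- genCCPattern(c(96, 96), 10, 24, seed = 4)
  expect_identical(pixels(a), pixels(b))
  expect_false(identical(pixels(a), pixels(genCCPattern(c(96, 96), 10, 24, seed = 5))))
  s1 <- applySpeckle(a, 2, seed = 3); s2 <- applySpeckle(a, 2, seed = 3)
  expect_identical(pixels(s1), pixels(s2))
  sc1 <- syntheticScene(c(96, 96), seed = 8)
  sc2 <- syntheticScene(c(96, 96), seed = 8)
  expect_identical(pixels(sc1@cleanImage), pixels(sc2@cleanImage))
  expect_identical(fdMask(sc1@fdTruth), fdMask(sc2@fdTruth))
})

test_that("the pattern's spectral peak sits at the requested spacing", {
  for (seed in c(1, 4, 7, 10)) {
    img <- genCCPattern(c(256, 256), 10, 24, seed = seed)
    est <- estimateICD(radialPowerSpectrum(extractROI(img, c(128, 128), 650)))
    expect_lte(abs(1 / est$icdUm - 1 / 24), 1 / 650 + 1e-9)  # within one bin
  }
  # a jitter-free lattice has a sharper peak than a strongly jittered one
  p0 <- genCCPattern(c(256, 256), 10, 24, jitter = 0, seed = 2)
  p3 <- genCCPattern(c(256, 256), 10, 24, jitter = 0.3, seed = 2)
  prom <- function(img) estimateICD(radialPowerSpectrum(
    extractROI(img, c(128, 128), 650)))$peakProminence
  expect_gt(prom(p0), prom(p3))
  # lobular variant keeps the lattice periodicity
  lb <- genCCPattern(c(200, 200), 10, 24, "lobular", seed = 4)
  expect_equal(estimateICD(radialPowerSpectrum(
    extractROI(lb, c(100, 100), 650)))$icdUm, 24, tolerance = 2)
  expect_error(genCCPattern(c(96, 96), 10, 15), "resolvability")
  expect_error(genCCPattern(c(96, 96), 10, 24, jitter = 0.9), "jitter")
})

test_that("speckle follows the Gamma multi-look statistics", {
  base <- EnFaceImage(matrix(30, 256, 256), 10)   # dim: clipping negligible
  sp <- applySpeckle(base, 1, seed = 5)
  cv <- sd(pixels(sp)) / mean(pixels(sp))
  expect_equal(cv, 1, tolerance = 0.1)            # CV = 1/sqrt(looks)
  sp4 <- applySpeckle(base, 4, seed = 5)
  expect_equal(sd(pixels(sp4)) / mean(pixels(sp4)), 0.5, tolerance = 0.1)
  expect_equal(mean(pixels(sp)), 30, tolerance = 1)
  # noiseless limit
  spInf <- applySpeckle(base, 1e6, seed = 5)
  expect_lte(sqrt(mean((pixels(spInf) - 30)^2)), 1)
  expect_error(applySpeckle(base, 0), "positive")
})

test_that("applyTransform matches an independent cross-correlation oracle", {
  img <- genCCPattern(c(128, 128), 10, 24, seed = 6)
  out <- applyTransform(img, TransformChain(translation = c(7, -4)))
  # out(y, x) = img(y + 7, x - 4): check by direct submatrix comparison
  expect_equal(pixels(out)[1:100, 10:120], pixels(img)[8:107, 6:116],
               tolerance = 1e-9)
  idn <- applyTransform(img, identityChain())
  expect_equal(pixels(idn), pixels(img), tolerance = 1e-9)
  expect_true(all(validMask(idn)))
  expect_false(all(validMask(out)))    # shifted rim is out of domain
})

test_that("planted deficits satisfy their density and shape contracts", {
  base <- genCCPattern(c(256, 256), 10, 24, seed = 1)
  pl <- plantFDs(base, 0.05, 1500, elongation = 2, seed = 3)
  fdd <- mean(fdMask(pl$truth))
  expect_gte(fdd, 0.045); expect_lte(fdd, 0.055)
  expect_equal(computeFDARI(labelFDs(pl$truth)), 2, tolerance = 0.15)
  expect_true(all(pixels(pl$image)[fdMask(pl$truth)] == 10))
  expect_error(plantFDs(EnFaceImage(matrix(100, 64, 64), 10), 0.5, 3e5),
               "placement failed")
  expect_error(plantFDs(base, 0.7, 1500), "density")
})

test_that("scene truth indices equal the morphometrics of the truth mask", {
  sc <- syntheticScene(c(128, 128), seed = 12)
  direct <- fdIndices(labelFDs(sc@fdTruth))
  expect_identical(sc@truthIndices, direct)
})

test_that("repeat stacks carry the stated motion and noise structure", {
  sc <- syntheticScene(c(128, 128), seed = 2)
  motions <- list(identityChain(), TransformChain(translation = c(4, -3)))
  st <- makeRepeatStack(sc, motions, looks = 2, seed = 40)
  expect_identical(nScans(st), 2L)
  st2 <- makeRepeatStack(sc, motions, looks = 2, seed = 40)
  expect_identical(pixels(st[[2]]), pixels(st2[[2]]))
  expect_error(makeRepeatStack(sc, list(TransformChain(translation = c(1, 0)))),
               "identity")
  # single-repeat stack is one noisy image
  st1 <- makeRepeatStack(sc, list(identityChain()), looks = 2, seed = 41)
  expect_identical(nScans(st1), 1L)
  # averaging the repeats correlates better with the clean scene than any
  # single repeat does
  motions5 <- c(list(identityChain()),
                lapply(list(c(5, 3), c(-4, 7), c(8, -6), c(-9, -2)),
                       function(s) TransformChain(translation = s)))
  st5 <- makeRepeatStack(sc, motions5, looks = 2, seed = 60)
  avg <- averageStack(st5, RegistrationConfig(stages = "translation"))
  cl <- as.vector(pixels(sc@cleanImage))
  corAvg <- cor(as.vector(pixels(avg)), cl)
  corSingles <- vapply(1:5, function(i) cor(as.vector(pixels(st5[[i]])), cl),
                       numeric(1))
  expect_gt(corAvg, max(corSingles))
})
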