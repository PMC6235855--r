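test_that("raster round trips are lossless up to bit-depth quantization", {
  td <- withr::local_tempdir()
  set.seed(1)
  img <- EnFaceImage(matrix(runif(64 * 64) * 255, 64, 64), 10)

  p16 <- file.path(td, "img16.tif")
  saveImage(img, p16, bitDepth = 16)
  back16 <- loadEnface(p16, 10)
  expect_lte(max(abs(pixels(back16) - pixels(img))), 255 / 65535 + 1e-9)
  expect_equal(pixelSize(back16), 10)

  p8 <- file.path(td, "img8.tif")
  saveImage(img, p8, bitDepth = 8)
  expect_lte(max(abs(pixels(loadEnface(p8, 10)) - pixels(img))), 255 / 255 / 2 + 1e-9)

  # a binary FD map saved at 8 bit holds exactly two levels
  pb <- file.path(td, "mask.png")
  saveImage(matrix(c(TRUE, FALSE), 16, 16), pb)
  expect_setequal(unique(as.vector(png::readPNG(pb))), c(0, 1))

  # constant-zero PNG loads as zeros
  pz <- file.path(td, "zero.png")
  png::writePNG(matrix(0, 16, 16), pz)
  expect_true(all(pixels(loadEnface(pz, 10)) == 0))
})

test_that("loadEnface rejects bad inputs with informative errors", {
  td <- withr::local_tempdir()
  rgb <- file.path(td, "rgb.png")
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), rgb)
  expect_error(loadEnface(rgb, 10), "multi-channel")
  expect_error(loadEnface(file.path(td, "absent.tif"), 10), "not found")
  expect_error(loadEnface(rgb, -1), "positive")
  expect_error(saveImage(matrix(1, 8, 8), file.path(td, "no/such/dir/x.tif")),
               "cannot write")
})

test_that("illumination normalization flattens a shading ramp", {
  set.seed(4)
  base <- pixels(genCCPattern(c(240, 240), 10, 24, seed = 2))
  ramp <- matrix(rep(seq(0.5, 1.5, length.out = 240), each = 240),
                 240, 240)                     # ramp[i, j] = factor of column j
  shaded <- EnFaceImage(base * ramp, 10)
  out <- normalizeIllumination(shaded, backgroundSigmaUm = 200)
  # interior blocks (> 2 sigma from the border, where the local-mean
  # background estimate of a linear ramp is unbiased)
  blockMean <- function(m, cols) mean(m[61:180, cols])
  before <- c(blockMean(pixels(shaded), 51:110), blockMean(pixels(shaded), 131:190))
  after <- c(blockMean(pixels(out), 51:110), blockMean(pixels(out), 131:190))
  expect_lt(abs(diff(after)) / mean(after), 0.05)
  expect_lt(abs(diff(after)) / mean(after), abs(diff(before)) / mean(before))
})

test_that("normalization is a no-op on already-uniform texture", {
  img <- genCCPattern(c(120, 120), 10, 24, seed = 3)
  out <- normalizeIllumination(img)
  expect_gte(cor(as.vector(pixels(out)), as.vector(pixels(img))), 0.999)
  # idempotence: a second pass changes values by < 1 gray level RMS
  out2 <- normalizeIllumination(out)
  expect_lt(sqrt(mean((pixels(out2) - pixels(out))^2)), 1)
})

test_that("normalization handles degenerate input with a warning, not an error", {
  img <- EnFaceImage(matrix(0, 32, 32), 10)
  expect_warning(out <- normalizeIllumination(img), "all-zero")
  expect_true(all(pixels(out) == 0))
  expect_error(normalizeIllumination(genCCPattern(c(64, 64), 10, 24), 30),
               ">= 5 pixels")
})
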