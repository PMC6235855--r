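test_that("mutual information matches hand-computed values and identities", {
  set.seed(2)
  x <- matrix(runif(64 * 64) * 255, 64, 64)
  # self-information equals the marginal histogram entropy
  p <- tabulate(floor(x / 8) + 1, 32) / length(x)
  expect_equal(mutualInformation(x, x, 32L), -sum(p[p > 0] * log2(p[p > 0])))
  # independence with a degenerate marginal
  expect_equal(mutualInformation(x, matrix(7, 64, 64)), 0)
  # symmetric
  y <- matrix(runif(64 * 64) * 255, 64, 64)
  expect_equal(mutualInformation(x, y), mutualInformation(y, x))
  expect_gte(mutualInformation(x, y), -1e-12)
  # 2 x 2 pair with joint {(0,0): 1/2, (255,255): 1/2} over 2 bins -> 1 bit
  m <- matrix(c(0, 0, 255, 255), 2, 2)
  expect_equal(mutualInformation(m, m, bins = 2L), 1)
  expect_error(mutualInformation(x, matrix(0, 8, 8)), "dimensions")
})

test_that("translation stage recovers known shifts on speckled phantoms", {
  clean <- ccFixture("scene")@cleanImage
  fixed <- ccFixture("fixed")
  for (shift in list(c(7, -4), c(-3, 8))) {
    mov <- applySpeckle(applyTransform(clean, TransformChain(translation = shift)),
                        2, seed = 20 + shift[1])
    ch <- registerTranslation(fixed, mov)
    # resampling convention: the fitted chain is the inverse of the motion
    expect_lt(max(abs(ch@translation + shift)), 0.5)
    expect_length(ch@flags, 0)
    # MI at the fitted shift is at least the MI of the unshifted pair
    expect_lte(ch@stagewiseCost[["translation"]], ch@stagewiseCost[["initial"]])
  }
})

test_that("translation on an identical pair is the identity", {
  fixed <- ccFixture("fixed")
  ch <- registerTranslation(fixed, fixed)
  expect_lt(sqrt(sum(ch@translation^2)), 0.1)
})

test_that("unrelated images are flagged instead of raising", {
  set.seed(1)
  noise <- EnFaceImage(matrix(runif(256 * 256) * 255, 256, 256), 10)
  ch <- registerTranslation(ccFixture("fixed"), noise)
  expect_true("no-signal" %in% ch@flags)
})

test_that("affine stage recovers rotation and scale, and respects init", {
  clean <- ccFixture("scene")@cleanImage
  fixed <- ccFixture("fixed")
  th <- 3 * pi / 180
  A <- 1.02 * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  mov <- applySpeckle(applyTransform(clean,
           TransformChain(translation = c(0, 0), affineMatrix = A,
                          affineOffset = c(0, 0))), 2, seed = 41)
  ch <- registerAffine(fixed, mov, registerTranslation(fixed, mov))
  expect_lt(abs(rotationDeg(ch@affineMatrix) + 3), 0.5)
  expect_lt(abs(sqrt(abs(det(ch@affineMatrix))) - 1 / 1.02), 0.01)
  expect_lte(ch@stagewiseCost[["affine"]], ch@stagewiseCost[["translation"]])

  # identical pair: affine stays at the identity
  ch0 <- registerAffine(fixed, fixed, registerTranslation(fixed, fixed))
  expect_lt(max(abs(ch0@affineMatrix - diag(2))), 0.01)

  # pure shift: matrix ~ identity, shift absorbed in the offset
  mv <- applySpeckle(applyTransform(clean, TransformChain(translation = c(5, 3))),
                     2, seed = 43)
  chs <- registerAffine(fixed, mv, registerTranslation(fixed, mv))
  expect_lt(max(abs(chs@affineMatrix - diag(2))), 0.01)
  expect_lt(max(abs(chs@affineOffset + c(5, 3))), 0.5)

  expect_error(registerAffine(fixed, mov, TransformChain(affineMatrix = diag(2),
                                                         center = c(1, 1))),
               NA)
})

test_that("B-spline stage recovers a smooth elastic field", {
  clean <- ccFixture("scene")@cleanImage
  fixed <- ccFixture("fixed")
  truth <- sinusoidChain(256, amplitude = 3, period = 100)
  mov <- applySpeckle(applyTransform(clean, truth), 2, seed = 77)
  tr <- registerTranslation(fixed, mov)
  af <- registerAffine(fixed, mov, tr)
  bs <- registerBspline(fixed, mov, af)
  expect_lt(compositionResidual(bs, truth), 1)
  expect_gt(compositionResidual(af, truth), compositionResidual(bs, truth))
  expect_lte(bs@stagewiseCost[["bspline"]], bs@stagewiseCost[["affine"]])
  expect_lte(max(abs(c(bs@bsplineDy, bs@bsplineDx))), 2 * 32)
  expect_false("foldover" %in% bs@flags)

  # identical pair: control displacements stay near zero
  bs0 <- registerBspline(fixed, fixed,
                         registerAffine(fixed, fixed,
                                        registerTranslation(fixed, fixed)))
  expect_lte(max(abs(c(bs0@bsplineDy, bs0@bsplineDx)), 0), 0.2)
})

test_that("the full cascade keeps stagewise cost non-increasing and resamples", {
  fixed <- ccFixture("fixed")
  r <- registerThreeStep(fixed, fixed)
  expect_true(all(diff(r$chain@stagewiseCost) <= 1e-9))
  expect_lte(sqrt(mean((pixels(r$registered) - pixels(fixed))^2)), 1)
  small <- EnFaceImage(matrix(1, 32, 32), 10)
  expect_error(registerThreeStep(fixed, small), "dimensions")
})

test_that("averaging uses valid contributors and respects degenerate cases", {
  fixed <- ccFixture("fixed")
  st <- ImageStack(list(fixed, fixed, fixed))
  expect_identical(pixels(averageStack(st, nAverage = 1)), pixels(fixed))
  av <- averageStack(st)
  expect_lt(max(abs(pixels(av) - pixels(fixed))), 1e-9)
  expect_error(averageStack(st, nAverage = 4), "nAverage")

  # shifted member: out-of-domain rim pixels keep the reference value
  clean <- ccFixture("scene")@cleanImage
  mov <- applySpeckle(applyTransform(clean, TransformChain(translation = c(10, 0))),
                      2, seed = 55)
  av2 <- averageStack(ImageStack(list(fixed, mov)))
  expect_true(all(is.finite(pixels(av2))))
  expect_identical(dim(pixels(av2)), dim(pixels(fixed)))
})
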