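test_that("fuzzy c-means separates well-separated regions exactly", {
  img <- matrix(50, 64, 64); img[, 33:64] <- 200
  m <- fcmCluster(img, 2)
  expect_lt(max(abs(centroids(m) - c(50, 200))), 1)
  expect_identical(hardLabels(m) == 2L, img == 200)
  expect_true(all(abs(rowSums(m@memberships) - 1) < 1e-6))
  expect_true(all(diff(m@objective) <= 1e-6))   # objective non-increasing

  m1 <- fcmCluster(img, 1)
  expect_equal(centroids(m1), mean(img))
  expect_true(all(m1@memberships == 1))
})

test_that("fcm recovers a seeded 3-Gaussian mixture with >= 95% accuracy", {
  set.seed(42)
  n <- 90 * 90
  lab <- sample(1:3, n, replace = TRUE)
  x <- matrix(pmax(0, pmin(255, rnorm(n, c(40, 128, 216)[lab], 15))), 90, 90)
  m <- fcmCluster(x, 3)
  expect_gte(mean(hardLabels(m) == lab), 0.95)
  expect_lt(max(abs(centroids(m) - c(40, 128, 216))), 5)
  expect_true(all(diff(m@objective) <= 1e-6))
  expect_true(all(diff(centroids(m)) > 0))
})

test_that("fcm centroids agree with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- c(rnorm(1500, 60, 10), rnorm(1500, 180, 10))
  img <- matrix(pmax(0, pmin(255, x)), 50, 60)
  ours <- centroids(fcmCluster(img, 2))
  ref <- sort(as.vector(e1071::cmeans(matrix(as.vector(img), ncol = 1),
                                      centers = 2, m = 2)$centers))
  expect_equal(ours, ref, tolerance = 0.01)
})

test_that("elbow rule finds the true component count and flags degeneracy", {
  set.seed(7)
  img <- matrix(rep(c(0, 120, 240), each = 32 * 96), 96, 96)
  img <- matrix(pmax(0, pmin(255, img + rnorm(96 * 96, 0, 5))), 96, 96)
  k <- elbowSelectK(img, kMax = 8)
  expect_identical(as.integer(k), 3L)
  expect_gte(attr(k, "explainedVariance"), 0.99)

  expect_warning(kc <- elbowSelectK(matrix(5, 32, 32)), "constant")
  expect_identical(as.integer(kc), 1L)
  expect_error(elbowSelectK(img, kMax = 1), "2..10")
  expect_error(elbowSelectK(img, threshold = 1.5), "\\(0, 1\\)")
})

test_that("the FD map is the darkest cluster and k = 1 is rejected", {
  img <- matrix(50, 64, 64); img[, 33:64] <- 200
  m <- fcmCluster(img, 2)
  fd <- extractFDMap(m, 10)
  expect_identical(fdMask(fd), img == 50)
  expect_equal(pixelSize(fd), 10)
  expect_error(extractFDMap(fcmCluster(img, 1), 10), "k must be >= 2")
})

test_that("cluster relabelling cannot change the FD map (centroid sorting)", {
  set.seed(11)
  img <- matrix(pmax(0, pmin(255, c(rnorm(2048, 40, 8), rnorm(2048, 200, 8)))),
                64, 64)
  fd1 <- fdMask(extractFDMap(fcmCluster(img, 3, seed = 1), 10))
  fd2 <- fdMask(extractFDMap(fcmCluster(img, 3, seed = 2), 10))
  expect_identical(fd1, fd2)
  expect_identical(fd1, fdMask(extractFDMap(fcmCluster(img[64:1, ], 3), 10))[64:1, ])
})

test_that("projection-artifact removal drops only vessel-covered components", {
  m <- matrix(FALSE, 50, 50)
  m[5:14, 5:14] <- TRUE          # under the vessel stripe
  m[30:34, 30:41] <- TRUE        # disjoint from it
  fd <- FDBinaryMap(m, 10)
  vessel <- matrix(FALSE, 50, 50); vessel[1:20, 1:20] <- TRUE

  out <- removeProjectionArtifacts(fd, vessel, 0.5)
  expect_false(any(fdMask(out)[5:14, 5:14]))
  expect_true(all(fdMask(out)[30:34, 30:41]))

  expect_identical(fdMask(removeProjectionArtifacts(fd, matrix(FALSE, 50, 50))), m)

  # overlapFrac = 0: any touching component is removed
  touch <- matrix(FALSE, 50, 50); touch[14, 14] <- TRUE
  out0 <- removeProjectionArtifacts(fd, touch, 0)
  expect_false(any(fdMask(out0)[5:14, 5:14]))
  expect_true(all(fdMask(out0)[30:34, 30:41]))

  expect_error(removeProjectionArtifacts(fd, matrix(FALSE, 10, 10)), "shape")
})

test_that("planted deficits are recovered from an averaged speckled scene", {
  scene <- syntheticScene(c(192, 192), seed = 21)
  # five aligned speckle realizations, averaged (segmentation-focused check)
  reps <- lapply(1:5, function(i) pixels(applySpeckle(scene@cleanImage, 2, seed = 30 + i)))
  avg <- EnFaceImage(Reduce(`+`, reps) / 5, 10)
  norm <- normalizeIllumination(avg)
  k <- suppressWarnings(elbowSelectK(norm))
  fd <- extractFDMap(fcmCluster(norm, k), 10)
  expect_gte(diceOverlap(fdMask(fd), fdMask(scene@fdTruth)), 0.8)
  expect_lt(abs(computeFDD(fd) - mean(fdMask(scene@fdTruth))), 0.02)
})
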