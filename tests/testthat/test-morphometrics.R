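test_that("labelling agrees with flood-fill and bwlabel oracles on random maps", {
  set.seed(13)
  for (i in 1:20) {
    h <- sample(16:48, 1); w <- sample(16:48, 1)
    mask <- matrix(runif(h * w) < runif(1, 0.1, 0.5), h, w)
    fd <- FDBinaryMap(mask, 10)
    for (conn in c(4L, 8L)) {
      cs <- labelFDs(fd, conn)
      oracle <- floodLabels(mask, conn)
      expect_identical(length(cs), max(oracle, 0L))
      # identical pixel partitions (compare as canonical label sets)
      ours <- lapply(cs@pixelIdx, sort)
      ref <- unname(split(which(mask), oracle[mask]))
      expect_setequal(sapply(ours, paste, collapse = ","),
                      sapply(lapply(ref, sort), paste, collapse = ","))
    }
    # EBImage's labeller (4-connected) as a second, independent reference
    expect_identical(length(labelFDs(fd, 4L)),
                     max(0L, as.integer(max(EBImage::bwlabel(mask * 1)))))
  }
})

test_that("component attributes match hand-computable fixtures", {
  # 10 x 10 solid square at 10 um/px
  m <- matrix(FALSE, 40, 40); m[11:20, 16:25] <- TRUE
  cs <- labelFDs(FDBinaryMap(m, 10))
  df <- fdComponents(cs)
  expect_equal(df$areaUm2, 10000)
  expect_equal(df$perimeterUm, 360)     # 36 unit boundary steps x 10 um
  # two diagonally touching pixels: one component at 8, two at 4
  dg <- matrix(FALSE, 10, 10); dg[3, 3] <- TRUE; dg[4, 4] <- TRUE
  expect_identical(length(labelFDs(FDBinaryMap(dg, 10), 8L)), 1L)
  expect_identical(length(labelFDs(FDBinaryMap(dg, 10), 4L)), 2L)
  # empty map
  expect_identical(length(labelFDs(FDBinaryMap(matrix(FALSE, 10, 10), 10))), 0L)
  # single pixel: axes = one pixel, perimeter = 4 pixel-units
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  d1 <- fdComponents(labelFDs(FDBinaryMap(one, 10)))
  expect_equal(d1$majorAxisUm, 10)
  expect_equal(d1$minorAxisUm, 10)
  expect_equal(d1$perimeterUm, 40)
})

test_that("aspect-ratio and complexity indices match analytic shapes", {
  ps <- 10
  expect_equal(computeFDARI(labelFDs(FDBinaryMap(rasterDisk(10), ps))), 1,
               tolerance = 0.05)
  # moments-equivalent ellipse of a 20/10 semi-axis ellipse
  ell <- outer(1:61, 1:61, function(y, x) ((y - 31) / 10)^2 + ((x - 31) / 20)^2 <= 1)
  expect_equal(computeFDARI(labelFDs(FDBinaryMap(ell, ps))), 2, tolerance = 0.1)
  # isoperimetric limits of the chain-code estimator
  for (r in c(10, 12, 14))
    expect_equal(computeFDCI(labelFDs(FDBinaryMap(rasterDisk(r), ps))), 1,
                 tolerance = 0.1)
  sq <- matrix(FALSE, 60, 60); sq[6:55, 6:55] <- TRUE
  expect_equal(computeFDCI(labelFDs(FDBinaryMap(sq, ps))), 4 / pi,
               tolerance = 0.1)
  # boundary roughening strictly increases FDCI
  rough <- rasterDisk(14); n <- nrow(rough); ctr <- (n + 1) / 2
  set.seed(3)
  for (k in 1:10) {
    th <- runif(1, 0, 2 * pi)
    for (d in 14:18) {
      y <- round(ctr + d * sin(th)); x <- round(ctr + d * cos(th))
      if (y >= 1 && y <= n && x >= 1 && x <= n) rough[y, x] <- TRUE
    }
  }
  expect_gt(computeFDCI(labelFDs(FDBinaryMap(rough, ps))),
            computeFDCI(labelFDs(FDBinaryMap(rasterDisk(14), ps))))
  empty <- labelFDs(FDBinaryMap(matrix(FALSE, 10, 10), ps))
  expect_error(computeFDARI(empty), "empty")
  expect_error(computeFDCI(empty), "empty")
})

test_that("density, number and size indices are exact pixel counts", {
  set.seed(17)
  for (i in 1:10) {
    mask <- matrix(runif(32 * 32) < 0.3, 32, 32)
    fd <- FDBinaryMap(mask, 10)
    expect_equal(computeFDD(fd), sum(mask) / length(mask))
    cs <- labelFDs(fd)
    nf <- computeFDNFDS(cs)
    expect_identical(nf$fdn, max(floodLabels(mask, 8L), 0L))
    if (nf$fdn > 0)
      expect_equal(nf$fdsUm2 * nf$fdn, sum(mask) * 100, tolerance = 1e-9)
    # consistency: fdd x image area = fdn x fds (pixel units)
    idx <- fdIndices(cs)
    expect_equal(idx$fdd * length(mask) * 100, idx$fdn * idx$fdsUm2,
                 tolerance = 1e-9)
  }
  expect_equal(computeFDD(FDBinaryMap(matrix(TRUE, 8, 8), 10)), 1)
  expect_equal(computeFDD(FDBinaryMap(matrix(FALSE, 8, 8), 10)), 0)
  e <- computeFDNFDS(labelFDs(FDBinaryMap(matrix(FALSE, 8, 8), 10)))
  expect_identical(e$fdn, 0L); expect_true(e$empty); expect_equal(e$fdsUm2, 0)
})

test_that("three known blobs give the hand-summed FDN and FDS", {
  m <- matrix(FALSE, 50, 50)
  m[2:4, 2:11] <- TRUE     # 30 px
  m[10:14, 20:29] <- TRUE  # 50 px
  m[30:36, 30:39] <- TRUE  # 70 px
  nf <- computeFDNFDS(labelFDs(FDBinaryMap(m, 10)))
  expect_identical(nf$fdn, 3L)
  expect_equal(nf$fdsUm2, 150 * 100 / 3)   # 5000 um^2
})

test_that("indices are invariant to pixel size except FDS ~ area scaling", {
  set.seed(19)
  mask <- matrix(runif(40 * 40) < 0.25, 40, 40)
  i1 <- fdIndices(labelFDs(FDBinaryMap(mask, 10)))
  i2 <- fdIndices(labelFDs(FDBinaryMap(mask, 20)))
  expect_equal(i1$fdd, i2$fdd)
  expect_identical(i1$fdn, i2$fdn)
  expect_equal(i1$fdari, i2$fdari)
  expect_equal(i1$fdci, i2$fdci)
  expect_equal(i2$fdsUm2 / i1$fdsUm2, 4)
})

test_that("the six functional maps are consistent with their components", {
  m <- matrix(FALSE, 50, 50); m[5:14, 5:14] <- TRUE; m[30:34, 30:41] <- TRUE
  cs <- labelFDs(FDBinaryMap(m, 10))
  maps <- generateFDMaps(cs)
  expect_identical(maps$binary, m)
  # nonzero support of every map within the binary mask
  for (nm in c("perimeter", "length", "aspectRatio", "complexity", "size"))
    expect_true(all(m[maps[[nm]] != 0]))
  # scalar maps constant per component; two components -> two nonzero values
  expect_identical(length(setdiff(unique(as.vector(maps$size)), 0)), 2L)
  for (i in 1:2)
    expect_identical(length(unique(maps$aspectRatio[cs@pixelIdx[[i]]])), 1L)
  # square's perimeter map is exactly its one-pixel boundary ring
  inner <- matrix(FALSE, 50, 50); inner[6:13, 6:13] <- TRUE
  sqOnly <- m; sqOnly[30:34, ] <- FALSE
  expect_true(all(maps$perimeter[sqOnly & !inner]))
  expect_false(any(maps$perimeter[inner]))
  # empty set -> six empty maps
  me <- generateFDMaps(labelFDs(FDBinaryMap(matrix(FALSE, 8, 8), 10)))
  expect_true(all(vapply(me, function(x) sum(x != 0) == 0, logical(1))))
})
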