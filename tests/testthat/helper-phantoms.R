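# Shared fixtures (built in code, cached per test run) and independent
# oracles used across the suite.

# one 256 x 256 honeycomb scene with planted deficits, reused by the
# registration/averaging/acceptance tests
ccFixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    val <- switch(name,
      scene = syntheticScene(c(256, 256), seed = 5),
      fixed = applySpeckle(ccFixture("scene")@cleanImage, 2, seed = 11),
      stop("unknown fixture ", name))
    cache[[name]] <- val
    val
  }
})

# brute-force connected-component labelling by stack-based flood fill;
# independent of the igraph-based implementation under test
floodLabels <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  nextLab <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    stack <- start
    lab[start] <- nextLab
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      py <- (p - 1L) %% h + 1L; px <- (p - 1L) %/% h + 1L
      for (o in offs) {
        y <- py + o[1]; x <- px + o[2]
        if (y >= 1 && y <= h && x >= 1 && x <= w) {
          q <- (x - 1L) * h + y
          if (mask[q] && lab[q] == 0L) { lab[q] <- nextLab; stack <- c(stack, q) }
        }
      }
    }
  }
  lab
}

diceOverlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

rasterDisk <- function(r, n = 2 * r + 11) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(y, x) (y - ctr)^2 + (x - ctr)^2 <= r^2)
}

# ground-truth sinusoidal B-spline motion used by the elastic-recovery tests
sinusoidChain <- function(n = 256, spacing = 32, amplitude = 3, period = 100) {
  g <- ccquant:::.bsplineGrid(n, spacing)
  pos <- g$origin + (seq_len(g$nNodes) - 1) * spacing
  TransformChain(
    translation = c(0, 0), affineMatrix = diag(2), affineOffset = c(0, 0),
    center = c((n + 1) / 2, (n + 1) / 2), bsplineSpacingPx = spacing,
    bsplineDy = outer(sin(2 * pi * pos / period), rep(1, g$nNodes)) * amplitude,
    bsplineDx = outer(rep(1, g$nNodes), cos(2 * pi * pos / period)) * amplitude,
    bsplineOrigin = c(g$origin, g$origin))
}

# mean |T_truth(T_recovered(p)) - p| over interior pixels: 0 for a perfect
# inverse recovery
compositionResidual <- function(recovered, truth, n = 256, margin = 16) {
  g <- ccquant:::.coordGrid(n, n)
  rec <- ccquant:::.evalTransform(recovered, g$Y, g$X)
  comp <- ccquant:::.evalTransform(truth, rec$Y, rec$X)
  inner <- as.vector(g$Y > margin & g$Y < n - margin &
                     g$X > margin & g$X < n - margin)
  mean(sqrt((comp$Y - g$Y)^2 + (comp$X - g$X)^2)[inner])
}

rotationDeg <- function(M) atan2(M[2, 1], M[1, 1]) * 180 / pi
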