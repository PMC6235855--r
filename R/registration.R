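## Three-step registration of repeated en face CC scans.
##
## Every stage minimizes the same cost C = -MI, the negative mutual
## information of the joint intensity histogram between the fixed image
## (scan 1) and the resampled moving image:
##   translation -> affine -> cubic B-spline free-form deformation.
## Stage results are guarded so the recorded stagewise cost never increases:
## a stage that fails to improve the cost is reverted and flagged.

## ---- mutual information ----------------------------------------------------

.miVectors <- function(a, b, bins) {
  ia <- floor(a * (bins / 256)); ia[ia >= bins] <- bins - 1; ia[ia < 0] <- 0
  ib <- floor(b * (bins / 256)); ib[ib >= bins] <- bins - 1; ib[ib < 0] <- 0
  joint <- tabulate(ia * bins + ib + 1L, nbins = bins * bins)
  n <- sum(joint)
  if (n == 0) return(0)
  p <- joint / n
  pm <- matrix(p, bins, bins)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  H(rowSums(pm)) + H(colSums(pm)) - H(p)
}

#' Mutual information between two images
#'
#' Computes I(A;B) = H(A) + H(B) - H(A,B) in bits from the joint intensity
#' histogram with \code{bins} x \code{bins} cells over the fixed [0, 255]
#' intensity range. This is the registration cost (negated); it is symmetric
#' in its arguments and non-negative up to floating error. Pixels marked
#' invalid in either image's validity mask are excluded.
#'
#' @param a,b \linkS4class{EnFaceImage} objects or numeric matrices of equal
#'   shape.
#' @param bins histogram bin count per axis (>= 2; default 32).
#' @return Mutual information in bits.
#' @examples
#' m <- matrix(runif(64 * 64) * 255, 64, 64)
#' mutualInformation(m, m) # equals the marginal histogram entropy of m
#' @export
mutualInformation <- function(a, b, bins = 32L) {
  va <- if (is(a, "EnFaceImage")) a@valid else NULL
  vb <- if (is(b, "EnFaceImage")) b@valid else NULL
  if (is(a, "EnFaceImage")) a <- a@pixels
  if (is(b, "EnFaceImage")) b <- b@pixels
  if (!identical(dim(a), dim(b)))
    stop("mutualInformation: images must share dimensions")
  if (bins < 2L) stop("mutualInformation: bins must be >= 2")
  keep <- TRUE
  if (!is.null(va)) keep <- keep & va
  if (!is.null(vb)) keep <- keep & vb
  if (isTRUE(keep)) .miVectors(as.vector(a), as.vector(b), as.integer(bins))
  else .miVectors(a[keep], b[keep], as.integer(bins))
}

## MI for an integer shift, via overlapping submatrices (no interpolation):
## moving sampled at (y + dy, x + dx)
.miIntShift <- function(f, m, fv, mv, dy, dx, bins) {
  h <- nrow(f); w <- ncol(f)
  yf <- max(1, 1 - dy):min(h, h - dy)
  xf <- max(1, 1 - dx):min(w, w - dx)
  if (length(yf) < 8 || length(xf) < 8) return(-Inf)
  fs <- f[yf, xf]; ms <- m[yf + dy, xf + dx]
  keep <- fv[yf, xf] & mv[yf + dy, xf + dx]
  .miVectors(fs[keep], ms[keep], bins)
}

## partial-volume mutual information: sample positions (Y, X) in the moving
## image spread their unit histogram mass over the 4 neighbouring pixels
## instead of interpolating intensities, so the cost varies smoothly with
## subpixel parameters without the interpolation-smoothing MI bias that
## pulls optima toward half-pixel offsets on speckled images
.miPV <- function(fvals, mpix, Y, X, bins, keepF = TRUE) {
  h <- nrow(mpix); w <- ncol(mpix)
  keep <- (Y >= 1 & X >= 1 & Y <= h & X <= w) & keepF
  if (sum(keep) < 64) return(NA_real_)
  Y <- Y[keep]; X <- X[keep]
  y0 <- pmin(pmax(floor(Y), 1), h - 1)
  x0 <- pmin(pmax(floor(X), 1), w - 1)
  fy <- pmin(pmax(Y - y0, 0), 1)
  fx <- pmin(pmax(X - x0, 0), 1)
  ia <- floor(fvals[keep] * (bins / 256))
  ia[ia >= bins] <- bins - 1; ia[ia < 0] <- 0
  binOf <- function(v) { b <- floor(v * (bins / 256)); b[b >= bins] <- bins - 1
                         b[b < 0] <- 0; b }
  i00 <- (x0 - 1) * h + y0
  idx <- c(ia * bins + binOf(mpix[i00]) + 1,
           ia * bins + binOf(mpix[i00 + 1]) + 1,
           ia * bins + binOf(mpix[i00 + h]) + 1,
           ia * bins + binOf(mpix[i00 + h + 1]) + 1)
  wts <- c((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
  rs <- rowsum(wts, idx)
  jt <- numeric(bins * bins)
  jt[as.integer(rownames(rs))] <- rs
  p <- jt / sum(jt)
  pm <- matrix(p, bins, bins, byrow = TRUE)   # rows = fixed bins
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  H(rowSums(pm)) + H(colSums(pm)) - H(p)
}

## cost of a chain: -MI (partial volume) between fixed and the moving image
## sampled through the chain, optional pixel stride for speed
.chainCost <- function(fixed, moving, chain, bins, stride = 1L) {
  h <- nrow(fixed@pixels); w <- ncol(fixed@pixels)
  ys <- seq(1L, h, by = stride); xs <- seq(1L, w, by = stride)
  Y <- matrix(rep(ys, length(xs)), length(ys))
  X <- matrix(rep(xs, each = length(ys)), length(ys))
  tc <- .evalTransform(chain, Y, X)
  fvals <- fixed@pixels[cbind(as.vector(Y), as.vector(X))]
  keepF <- fixed@valid[cbind(as.vector(Y), as.vector(X))]
  mi <- .miPV(fvals, moving@pixels, as.vector(tc$Y), as.vector(tc$X), bins,
              keepF)
  if (is.na(mi)) Inf else -mi
}

## light Gaussian smoothing, clamped to the non-negative intensity range
.smooth1 <- function(m) pmax(EBImage::gblur(m, 1, boundary = "replicate"), 0)

## chain cost on lightly smoothed copies of both images; used only for the
## no-signal diagnostic, never for the recorded stagewise cost
.smoothedChainCost <- function(fixed, moving, chain, bins) {
  fs <- EnFaceImage(.smooth1(fixed@pixels), fixed@pixelSizeUm, fixed@valid)
  ms <- EnFaceImage(.smooth1(moving@pixels), moving@pixelSizeUm, moving@valid)
  .chainCost(fs, ms, chain, bins)
}

## ---- pyramids --------------------------------------------------------------

.downsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w)]
  0.25 * (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
          m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)])
}

.pyramid <- function(img, levels) {
  p <- list(list(pix = img@pixels, valid = img@valid))
  for (l in seq_len(levels - 1L)) {
    prev <- p[[l]]
    if (min(dim(prev$pix)) < 64) break
    p[[l + 1L]] <- list(pix = .downsample2(prev$pix),
                        valid = .downsample2(prev$valid * 1) > 0.99)
  }
  p
}

## ---- translation stage -----------------------------------------------------

#' Translation registration
#'
#' Finds the (dy, dx) shift maximizing mutual information over a
#' multi-resolution integer search, refined to subpixel precision by
#' parabolic interpolation of the integer-shift MI surface. The returned
#' shift never decreases MI relative to the unshifted pair. When even the
#' best shift leaves the mutual information near the finite-sample bias
#' floor (unrelated images), the chain is flagged \code{"no-signal"}
#' instead of raising an error.
#'
#' @param fixed,moving \linkS4class{EnFaceImage} objects of equal shape and
#'   pixel size.
#' @param cfg a \linkS4class{RegistrationConfig}.
#' @return A \linkS4class{TransformChain} with the translation stage filled.
#' @export
registerTranslation <- function(fixed, moving, cfg = RegistrationConfig()) {
  .checkPair(fixed, moving)
  bins <- cfg@miBins
  ## search on lightly smoothed copies: smoothing lifts the MI peak of
  ## heavily speckled pairs well above the bias floor without displacing it
  ## (recorded stagewise costs below still use the raw images)
  fS <- EnFaceImage(.smooth1(fixed@pixels), fixed@pixelSizeUm, fixed@valid)
  mS <- EnFaceImage(.smooth1(moving@pixels), moving@pixelSizeUm, moving@valid)
  pyr <- .pyramid(fS, cfg@pyramidLevels)
  pyrM <- .pyramid(mS, cfg@pyramidLevels)
  L <- min(length(pyr), length(pyrM))
  best <- c(0, 0)
  for (l in L:1) {
    f <- pyr[[l]]$pix;  fv <- pyr[[l]]$valid
    m <- pyrM[[l]]$pix; mv <- pyrM[[l]]$valid
    r <- if (l == L) ceiling(cfg@maxShiftPx / 2^(l - 1)) + 2L else 2L
    ctr <- round(best / 2^(l - 1))
    cand <- expand.grid(dy = ctr[1] + (-r):r, dx = ctr[2] + (-r):r)
    mis <- mapply(function(dy, dx) .miIntShift(f, m, fv, mv, dy, dx, bins),
                  cand$dy, cand$dx)
    k <- which.max(mis)
    best <- c(cand$dy[k], cand$dx[k]) * 2^(l - 1)
  }
  ## subpixel refinement: parabolic interpolation of the integer-shift MI
  ## surface (integer-shift MI needs no interpolation, so it carries neither
  ## the linear-interpolation nor the partial-volume grid bias)
  f <- fS@pixels; m <- mS@pixels
  miAt <- function(dy, dx) .miIntShift(f, m, fixed@valid, moving@valid,
                                       dy, dx, bins)
  m0 <- miAt(best[1], best[2])
  sub <- c(0, 0)
  my <- c(miAt(best[1] - 1, best[2]), m0, miAt(best[1] + 1, best[2]))
  mx <- c(miAt(best[1], best[2] - 1), m0, miAt(best[1], best[2] + 1))
  vertex <- function(v) {
    den <- v[1] - 2 * v[2] + v[3]
    if (!all(is.finite(v)) || den >= -1e-12) return(0)
    max(-0.5, min(0.5, 0.5 * (v[1] - v[3]) / den))
  }
  sub <- c(vertex(my), vertex(mx))
  center <- c((nrow(fixed@pixels) + 1) / 2, (ncol(fixed@pixels) + 1) / 2)
  chain <- TransformChain(translation = best + sub, center = center)
  c0 <- .chainCost(fixed, moving,
                   TransformChain(translation = c(0, 0), center = center), bins)
  cT <- .chainCost(fixed, moving, chain, bins)
  if (cT > c0) {  # guard: never worse than the unshifted pair
    chain <- TransformChain(translation = c(0, 0), center = center)
    cT <- c0
  }
  chain@stagewiseCost <- c(initial = c0, translation = cT)
  ## signal check on lightly smoothed images (smoothing lifts the aligned
  ## MI of speckled pairs far above the finite-sample bias floor while
  ## leaving unrelated images at it): the aligned MI must clearly beat the
  ## MI of deliberately misaligned probes
  miSm <- m0
  r <- cfg@maxShiftPx + 4L
  probes <- rbind(c(r, r), c(r, -r), c(-r, r), c(-r, -r),
                  c(0, 2 * r), c(0, -2 * r), c(2 * r, 0), c(-2 * r, 0))
  floorMi <- median(apply(probes, 1, function(p) miAt(p[1], p[2])),
                    na.rm = TRUE)
  chain@miFloor <- max(floorMi, 1e-6)
  if (miSm < 1.8 * chain@miFloor) chain@flags <- "no-signal"
  chain
}

.checkPair <- function(fixed, moving) {
  stopifnot(is(fixed, "EnFaceImage"), is(moving, "EnFaceImage"))
  if (!identical(dim(fixed@pixels), dim(moving@pixels)))
    stop("registration: fixed and moving images must share dimensions")
  if (fixed@pixelSizeUm != moving@pixelSizeUm)
    stop("registration: fixed and moving images must share pixel size")
}

## ---- affine stage ----------------------------------------------------------

#' Affine registration
#'
#' Refines a translation initialization into a full affine map (scaling,
#' rotation, shearing plus offset) by continuous Nelder-Mead minimization of
#' the negative mutual information, coarse-to-fine over the image pyramid.
#' Degenerate candidate matrices (|det| <= 1e-6) are rejected during the
#' search. If the fitted affine fails to improve on the translation-stage
#' cost it is reverted to the initialization and flagged
#' \code{"affine-no-gain"}, keeping the stagewise cost non-increasing.
#'
#' @param fixed,moving \linkS4class{EnFaceImage} objects of equal shape.
#' @param init \linkS4class{TransformChain} containing a translation stage.
#' @param cfg a \linkS4class{RegistrationConfig}.
#' @return A \linkS4class{TransformChain} with the affine stage filled.
#' @export
registerAffine <- function(fixed, moving, init, cfg = RegistrationConfig()) {
  .checkPair(fixed, moving)
  if (!"translation" %in% init@stages)
    stop("registerAffine: init must contain a translation stage")
  bins <- cfg@miBins
  h <- nrow(fixed@pixels); w <- ncol(fixed@pixels)
  ## optimize on lightly smoothed copies (cf. registerTranslation); the
  ## stage guard and recorded cost below use the raw images
  fS <- EnFaceImage(.smooth1(fixed@pixels), fixed@pixelSizeUm, fixed@valid)
  mS <- EnFaceImage(.smooth1(moving@pixels), moving@pixelSizeUm, moving@valid)
  pyrF <- .pyramid(fS, 2L); pyrM <- .pyramid(mS, 2L)
  L <- min(length(pyrF), length(pyrM))
  par <- c(0, 0, 0, 0, init@translation)   # (dA11, dA12, dA21, dA22, by, bx)
  ## coarse rotation/scale sweep at the coarsest level to step over the
  ## partial-volume cost bump at the exact identity
  {
    l <- L; fsc <- 2^(l - 1)
    fi <- EnFaceImage(pyrF[[l]]$pix, fixed@pixelSizeUm * fsc, pyrF[[l]]$valid)
    mo <- EnFaceImage(pyrM[[l]]$pix, fixed@pixelSizeUm * fsc, pyrM[[l]]$valid)
    ctr <- c((nrow(fi@pixels) + 1) / 2, (ncol(fi@pixels) + 1) / 2)
    b0 <- init@translation / fsc
    bestCost <- Inf
    for (deg in seq(-5, 5, by = 1)) for (sc in seq(0.97, 1.03, by = 0.01)) {
      th <- deg * pi / 180
      M <- sc * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                       byrow = TRUE)
      ch <- TransformChain(translation = b0, affineMatrix = M,
                           affineOffset = b0, center = ctr)
      cc <- .chainCost(fi, mo, ch, bins)
      if (cc < bestCost) { bestCost <- cc; par <- c(as.vector(t(M - diag(2))),
                                                    init@translation) }
    }
  }
  for (l in L:1) {
    f <- 2^(l - 1)
    fi <- EnFaceImage(pyrF[[l]]$pix, fixed@pixelSizeUm * f, pyrF[[l]]$valid)
    mo <- EnFaceImage(pyrM[[l]]$pix, fixed@pixelSizeUm * f, pyrM[[l]]$valid)
    ctr <- c((nrow(fi@pixels) + 1) / 2, (ncol(fi@pixels) + 1) / 2)
    stride <- if (l == 1L && h * w > 160^2) 2L else 1L
    obj <- function(p) {
      A <- diag(2) + matrix(p[1:4], 2, 2, byrow = TRUE)
      if (abs(det(A)) <= 1e-6) return(Inf)
      ch <- TransformChain(translation = p[5:6], affineMatrix = A,
                           affineOffset = p[5:6], center = ctr)
      .chainCost(fi, mo, ch, bins, stride = stride)
    }
    p0 <- par; p0[5:6] <- p0[5:6] / f
    opt <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = cfg@maxIterations, reltol = 1e-8,
                                parscale = c(rep(0.02, 4), 1, 1)))
    par <- opt$par; par[5:6] <- par[5:6] * f
  }
  center <- c((h + 1) / 2, (w + 1) / 2)
  A <- diag(2) + matrix(par[1:4], 2, 2, byrow = TRUE)
  chain <- TransformChain(translation = init@translation, affineMatrix = A,
                          affineOffset = par[5:6], center = center)
  costT <- unname(init@stagewiseCost["translation"])
  if (!length(costT) || is.na(costT))
    costT <- .chainCost(fixed, moving, init, bins)
  costA <- .chainCost(fixed, moving, chain, bins)
  flags <- init@flags
  if (costA > costT + 1e-9) {   # revert: affine did not improve the cost
    chain <- TransformChain(translation = init@translation,
                            affineMatrix = diag(2),
                            affineOffset = init@translation, center = center)
    costA <- costT
    flags <- c(flags, "affine-no-gain")
  }
  chain@stagewiseCost <- c(init@stagewiseCost, affine = costA)
  chain@miFloor <- init@miFloor
  if (length(chain@miFloor) && "no-signal" %in% flags &&
      -.smoothedChainCost(fixed, moving, chain, bins) >= 1.8 * chain@miFloor)
    flags <- setdiff(flags, "no-signal")   # affine alignment restored signal
  chain@flags <- flags
  chain
}

## ---- B-spline stage --------------------------------------------------------

#' B-spline free-form registration
#'
#' Refines an affine initialization with a cubic B-spline free-form
#' deformation on a regular control lattice (default spacing 32 px),
#' composed after the affine stage. Control-point displacements are
#' optimized by coordinate descent on the mutual-information cost evaluated
#' over each node's local support window, with a descending step schedule;
#' displacements are capped at \code{bsplineCapFactor} times the grid
#' spacing to prevent folding. A final global MI check scales the field
#' back (and ultimately reverts it, flag \code{"bspline-no-gain"}) if it
#' does not improve on the affine-stage cost, so the stagewise cost is
#' non-increasing. A non-positive Jacobian determinant anywhere raises the
#' \code{"foldover"} flag on the result rather than an error.
#'
#' @param fixed,moving \linkS4class{EnFaceImage} objects of equal shape.
#' @param init \linkS4class{TransformChain} with translation and affine
#'   stages.
#' @param cfg a \linkS4class{RegistrationConfig}.
#' @return A \linkS4class{TransformChain} with the B-spline stage filled.
#' @export
registerBspline <- function(fixed, moving, init, cfg = RegistrationConfig()) {
  .checkPair(fixed, moving)
  if (!all(c("translation", "affine") %in% init@stages))
    stop("registerBspline: init must contain translation and affine stages")
  bins <- cfg@miBins
  h <- nrow(fixed@pixels); w <- ncol(fixed@pixels)
  s <- cfg@bsplineGridSpacingPx
  cap <- cfg@bsplineCapFactor * s
  gy <- .bsplineGrid(h, s); gx <- .bsplineGrid(w, s)
  nY <- gy$nNodes; nX <- gx$nNodes
  By <- .bsplineBasis(seq_len(h), gy$origin, s, nY)
  Bx <- .bsplineBasis(seq_len(w), gx$origin, s, nX)
  Dy <- matrix(0, nY, nX); Dx <- matrix(0, nY, nX)

  ## affine part of the coordinate map, computed once
  g <- .coordGrid(h, w)
  base <- .evalTransform(init, g$Y, g$X)
  posY <- gy$origin + (seq_len(nY) - 1) * s
  posX <- gx$origin + (seq_len(nX) - 1) * s

  ## local windows hold few samples, so the raw speckle and a fine joint
  ## histogram would drown the alignment signal in finite-sample MI bias:
  ## evaluate the local cost on lightly smoothed images with a coarser
  ## histogram (the global acceptance guard below still uses the raw images)
  fpix <- .smooth1(fixed@pixels)
  mpix <- .smooth1(moving@pixels)
  locBins <- min(bins, 16L)

  localCost <- function(rows, cols, Dy, Dx) {
    Byr <- By[rows, , drop = FALSE]; Bxc <- Bx[cols, , drop = FALSE]
    Y2 <- base$Y[rows, cols] + Byr %*% Dy %*% t(Bxc)
    X2 <- base$X[rows, cols] + Byr %*% Dx %*% t(Bxc)
    mi <- .miPV(as.vector(fpix[rows, cols]), mpix, as.vector(Y2),
                as.vector(X2), locBins, as.vector(fixed@valid[rows, cols]))
    if (is.na(mi)) Inf else -mi
  }

  deltas <- c(4, 2, 1, 0.5, 0.25)
  deltas <- deltas[deltas <= cap]
  for (d in deltas) {
    for (i in seq_len(nY)) {
      rlo <- max(1, floor(posY[i] - s)); rhi <- min(h, ceiling(posY[i] + s))
      if (rhi - rlo < 12) next
      rows <- rlo:rhi
      for (j in seq_len(nX)) {
        clo <- max(1, floor(posX[j] - s)); chi <- min(w, ceiling(posX[j] + s))
        if (chi - clo < 12) next
        cols <- clo:chi
        cur <- localCost(rows, cols, Dy, Dx)
        moves <- list(c(d, 0), c(-d, 0), c(0, d), c(0, -d))
        for (mv in moves) {
          ny <- max(-cap, min(cap, Dy[i, j] + mv[1]))
          nx <- max(-cap, min(cap, Dx[i, j] + mv[2]))
          if (ny == Dy[i, j] && nx == Dx[i, j]) next
          D2y <- Dy; D2y[i, j] <- ny
          D2x <- Dx; D2x[i, j] <- nx
          cc <- localCost(rows, cols, D2y, D2x)
          if (cc < cur - 1e-5) { Dy <- D2y; Dx <- D2x; cur <- cc }
        }
      }
    }
  }

  mkChain <- function(Dy, Dx)
    TransformChain(translation = init@translation,
                   affineMatrix = init@affineMatrix,
                   affineOffset = init@affineOffset, center = init@center,
                   bsplineSpacingPx = s, bsplineDy = Dy, bsplineDx = Dx,
                   bsplineOrigin = c(gy$origin, gx$origin))
  costA <- unname(init@stagewiseCost["affine"])
  if (!length(costA) || is.na(costA))
    costA <- .chainCost(fixed, moving, init, bins)
  chain <- mkChain(Dy, Dx)
  costB <- .chainCost(fixed, moving, chain, bins)
  scale <- 1
  while (costB > costA + 1e-9 && scale > 0.2) {  # global MI acceptance guard
    scale <- scale / 2
    chain <- mkChain(Dy * scale, Dx * scale)
    costB <- .chainCost(fixed, moving, chain, bins)
  }
  flags <- init@flags
  if (costB > costA + 1e-9) {
    chain <- mkChain(matrix(0, nY, nX), matrix(0, nY, nX))
    costB <- costA
    flags <- c(flags, "bspline-no-gain")
  }
  if (.minJacobian(chain, h, w) <= 0) flags <- c(flags, "foldover")
  chain@stagewiseCost <- c(init@stagewiseCost, bspline = costB)
  chain@miFloor <- init@miFloor
  if (length(chain@miFloor) && "no-signal" %in% flags &&
      -.smoothedChainCost(fixed, moving, chain, bins) >= 1.8 * chain@miFloor)
    flags <- setdiff(flags, "no-signal")
  chain@flags <- flags
  chain
}

## ---- full cascade and averaging --------------------------------------------

#' Three-step registration
#'
#' Runs translation, affine and B-spline registration in order (or the
#' subset named in \code{cfg@stages}), then resamples the moving image into
#' the fixed frame with bilinear interpolation. Out-of-domain pixels are
#' marked in the validity mask of the returned image. Stage diagnostic
#' flags propagate to the returned chain.
#'
#' @param fixed,moving \linkS4class{EnFaceImage} objects of equal shape and
#'   pixel size.
#' @param cfg a \linkS4class{RegistrationConfig}.
#' @return A list with elements \code{chain} (\linkS4class{TransformChain})
#'   and \code{registered} (\linkS4class{EnFaceImage}).
#' @export
registerThreeStep <- function(fixed, moving, cfg = RegistrationConfig()) {
  .checkPair(fixed, moving)
  chain <- registerTranslation(fixed, moving, cfg)
  if ("affine" %in% cfg@stages)
    chain <- registerAffine(fixed, moving, chain, cfg)
  if ("bspline" %in% cfg@stages && "affine" %in% cfg@stages)
    chain <- registerBspline(fixed, moving, chain, cfg)
  list(chain = chain, registered = .warpByChain(moving, chain))
}

## register scans 2..n to scan 1; returns registered images + chains
.registerAll <- function(stack, cfg, n = nScans(stack)) {
  fixed <- stack[[1]]
  out <- vector("list", n)
  out[[1]] <- list(chain = NULL, registered = fixed)
  if (n >= 2L) for (i in 2:n) out[[i]] <- registerThreeStep(fixed, stack[[i]], cfg)
  out
}

#' Register and average repeated scans
#'
#' Registers scans 2..\code{nAverage} to the first scan (the reference, per
#' the acquisition-order convention) with the full three-step cascade and
#' returns the pixelwise arithmetic mean over each pixel's valid
#' contributors, which avoids rim artifacts from out-of-domain zero fill.
#' \code{nAverage = 1} returns the first scan unchanged. Members whose
#' registration carries the \code{"no-signal"} flag are excluded from the
#' average (an error is raised if none remain).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param cfg a \linkS4class{RegistrationConfig}.
#' @param nAverage number of scans to average (1..stack length).
#' @return The averaged \linkS4class{EnFaceImage}; attribute
#'   \code{"chains"} carries the fitted transforms.
#' @export
averageStack <- function(stack, cfg = RegistrationConfig(),
                         nAverage = nScans(stack)) {
  stopifnot(is(stack, "ImageStack"))
  if (nAverage < 1L || nAverage > nScans(stack))
    stop("averageStack: nAverage must lie in 1..", nScans(stack))
  regs <- .registerAll(stack, cfg, nAverage)
  .cumulativeAverage(regs, nAverage)
}

.cumulativeAverage <- function(regs, n) {
  fixed <- regs[[1]]$registered
  acc <- fixed@pixels * fixed@valid
  cnt <- fixed@valid * 1
  used <- 1L
  if (n >= 2L) for (i in 2:n) {
    ch <- regs[[i]]$chain
    if (!is.null(ch) && "no-signal" %in% ch@flags) next
    im <- regs[[i]]$registered
    acc <- acc + im@pixels * im@valid
    cnt <- cnt + im@valid
    used <- used + 1L
  }
  if (used == 0L || max(cnt) == 0) stop("averageStack: no converged members")
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- fixed@pixels[cnt == 0]
  res <- EnFaceImage(out, fixed@pixelSizeUm, valid = cnt > 0)
  attr(res, "chains") <- lapply(regs[seq_len(n)], function(r) r$chain)
  attr(res, "nUsed") <- used
  res
}
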