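## Geometry engine shared by the registration cascade and the synthetic
## motion generator: bilinear sampling, cubic B-spline free-form
## deformation, transform evaluation and image warping.
##
## Convention: a TransformChain maps fixed-image coordinates (y = row,
## x = col, 1-based pixel centres) to the moving-image coordinates at which
## the output value is sampled:
##   T(p) = A (p - c) + c + b + d(p)
## with A the affine matrix (identity until the affine stage is fitted),
## b the offset (the translation until the affine stage refines it), c the
## image centre and d(p) the cubic B-spline displacement field.

.bilinearSample <- function(img, Y, X) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(Y); x0 <- floor(X)
  fy <- Y - y0; fx <- X - x0
  ok <- Y >= 1 & X >= 1 & Y <= h & X <= w
  y0c <- pmin(pmax(y0, 1L), h - 1L)
  x0c <- pmin(pmax(x0, 1L), w - 1L)
  fy <- pmin(pmax(Y - y0c, 0), 1)
  fx <- pmin(pmax(X - x0c, 0), 1)
  i00 <- (x0c - 1) * h + y0c
  v <- (1 - fy) * (1 - fx) * img[i00] + fy * (1 - fx) * img[i00 + 1] +
       (1 - fy) * fx * img[i00 + h] + fy * fx * img[i00 + h + 1]
  list(values = v, inside = ok)
}

## cubic B-spline kernel, support |t| < 2
.bspline3 <- function(t) {
  a <- abs(t)
  out <- numeric(length(a))
  i1 <- a <= 1
  out[i1] <- 2 / 3 - a[i1]^2 + a[i1]^3 / 2
  i2 <- a > 1 & a < 2
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

## basis matrix: rows = coordinates, cols = control nodes at
## origin + (j - 1) * spacing
.bsplineBasis <- function(coords, origin, spacing, nNodes) {
  pos <- origin + (seq_len(nNodes) - 1) * spacing
  B <- outer(coords, pos, function(y, p) .bspline3((y - p) / spacing))
  B
}

## node layout covering pixel range [1, n] with cubic support
.bsplineGrid <- function(n, spacing) {
  k <- ceiling((n - 1) / spacing)
  origin <- 1 - 2 * spacing
  nNodes <- k + 5L          # nodes at origin + 0..(k+4) spacings
  list(origin = origin, nNodes = as.integer(nNodes))
}

## evaluate the chain at coordinate matrices/vectors Y, X (fixed frame)
.evalTransform <- function(chain, Y, X) {
  A <- chain@affineMatrix
  b <- if ("affine" %in% chain@stages) chain@affineOffset else chain@translation
  cy <- chain@center[1]; cx <- chain@center[2]
  Y2 <- A[1, 1] * (Y - cy) + A[1, 2] * (X - cx) + cy + b[1]
  X2 <- A[2, 1] * (Y - cy) + A[2, 2] * (X - cx) + cx + b[2]
  if ("bspline" %in% chain@stages && length(chain@bsplineDy)) {
    s <- chain@bsplineSpacingPx
    oy <- chain@bsplineOrigin[1]; ox <- chain@bsplineOrigin[2]
    if (is.matrix(Y) && nrow(Y) > 1 && ncol(Y) > 1 &&
        all(Y[, 1] == Y[, ncol(Y)]) && all(X[1, ] == X[nrow(X), ])) {
      ## separable grid: tensor-product evaluation
      By <- .bsplineBasis(Y[, 1], oy, s, nrow(chain@bsplineDy))
      Bx <- .bsplineBasis(X[1, ], ox, s, ncol(chain@bsplineDy))
      Y2 <- Y2 + By %*% chain@bsplineDy %*% t(Bx)
      X2 <- X2 + By %*% chain@bsplineDx %*% t(Bx)
    } else {
      By <- .bsplineBasis(as.vector(Y), oy, s, nrow(chain@bsplineDy))
      Bx <- .bsplineBasis(as.vector(X), ox, s, ncol(chain@bsplineDy))
      dy <- rowSums((By %*% chain@bsplineDy) * Bx)
      dx <- rowSums((By %*% chain@bsplineDx) * Bx)
      Y2 <- Y2 + dy; X2 <- X2 + dx
    }
  }
  list(Y = Y2, X = X2)
}

.coordGrid <- function(h, w) {
  list(Y = matrix(rep(seq_len(h), w), h, w),
       X = matrix(rep(seq_len(w), each = h), h, w))
}

## warp an EnFaceImage by a chain; out-of-domain pixels get `fill` and are
## marked invalid
.warpByChain <- function(img, chain, fill = 0) {
  p <- img@pixels
  g <- .coordGrid(nrow(p), ncol(p))
  tc <- .evalTransform(chain, g$Y, g$X)
  s <- .bilinearSample(p, tc$Y, tc$X)
  out <- matrix(s$values, nrow(p), ncol(p))
  valid <- matrix(s$inside, nrow(p), ncol(p))
  out[!valid] <- fill
  out[out < 0] <- 0
  EnFaceImage(out, img@pixelSizeUm, valid = valid)
}

## minimum Jacobian determinant of the chain over a coarse pixel grid
.minJacobian <- function(chain, h, w, step = 4) {
  ys <- seq(2, h - 1, by = step); xs <- seq(2, w - 1, by = step)
  g <- list(Y = matrix(rep(ys, length(xs)), length(ys)),
            X = matrix(rep(xs, each = length(ys)), length(ys)))
  e <- 0.5
  ty1 <- .evalTransform(chain, g$Y + e, g$X); ty0 <- .evalTransform(chain, g$Y - e, g$X)
  tx1 <- .evalTransform(chain, g$Y, g$X + e); tx0 <- .evalTransform(chain, g$Y, g$X - e)
  dyy <- (ty1$Y - ty0$Y) / (2 * e); dxy <- (ty1$X - ty0$X) / (2 * e)
  dyx <- (tx1$Y - tx0$Y) / (2 * e); dxx <- (tx1$X - tx0$X) / (2 * e)
  min(dyy * dxx - dxy * dyx)
}

#' Warp an image by a transform chain
#'
#' Applies a \linkS4class{TransformChain} to an image using the same
#' composition order and bilinear interpolation as the registration
#' resampler, so that registering \code{(img, applyTransform(img, t))}
#' recovers the inverse of \code{t} within the cascade's tolerances. Pixels
#' mapped from outside the source domain are zero-filled and marked invalid
#' in the output's validity mask.
#'
#' @param img an \linkS4class{EnFaceImage}.
#' @param chain a \linkS4class{TransformChain}; a chain whose \code{center}
#'   is unset (c(0, 0)) is applied about the image centre.
#' @return The warped \linkS4class{EnFaceImage}.
#' @export
applyTransform <- function(img, chain) {
  stopifnot(is(img, "EnFaceImage"), is(chain, "TransformChain"))
  h <- nrow(img@pixels); w <- ncol(img@pixels)
  if (all(chain@center == 0)) chain@center <- c((h + 1) / 2, (w + 1) / 2)
  if ("bspline" %in% chain@stages && length(chain@bsplineDy) &&
      .minJacobian(chain, h, w) <= 0)
    stop("applyTransform: transform folds over (non-positive Jacobian)")
  .warpByChain(img, chain)
}
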