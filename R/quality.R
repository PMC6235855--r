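## Image-quality metrics used to quantify the benefit of registration and
## averaging: global entropy, global standard deviation, local texture
## correlation (gray-level co-occurrence) and PSNR against the full-stack
## average.

.grayHist256 <- function(p) {
  lev <- floor(p); lev[lev > 255] <- 255; lev[lev < 0] <- 0
  tabulate(lev + 1L, nbins = 256L)
}

#' Global entropy of an image
#'
#' Shannon entropy of the 256-level gray histogram, normalized by
#' log2(256) = 8 bits so the value lies in [0, 1] (1 = uniform histogram,
#' 0 = constant image). Decreasing entropy with more averaging reflects
#' speckle suppression.
#'
#' @param img an \linkS4class{EnFaceImage} or numeric matrix in [0, 255].
#' @return Normalized entropy in [0, 1].
#' @export
globalEntropy <- function(img) {
  if (is(img, "EnFaceImage")) img <- img@pixels
  cnt <- .grayHist256(img)
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p)) / 8
}

#' Global standard deviation of an image
#'
#' Population standard deviation of pixel intensities on the [0, 255]
#' scale; decreases as averaging smooths speckle.
#'
#' @param img an \linkS4class{EnFaceImage} or numeric matrix.
#' @return Standard deviation in gray levels.
#' @export
globalStd <- function(img) {
  if (is(img, "EnFaceImage")) img <- img@pixels
  sqrt(mean((img - mean(img))^2))
}

## symmetric GLCM correlation of one quantized block over 4 directions
.glcmCorrelation <- function(q, nLevels) {
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  vals <- numeric(0)
  for (o in offs) {
    h <- nrow(q); w <- ncol(q)
    ys <- seq_len(h - o[1])
    xs <- if (o[2] >= 0) seq_len(w - o[2]) else (1 - o[2]):w
    a <- q[ys, xs]; b <- q[ys + o[1], xs + o[2]]
    i <- c(a, b); j <- c(b, a)            # symmetric accumulation
    jt <- tabulate((i - 1L) * nLevels + j, nbins = nLevels * nLevels)
    p <- jt / sum(jt)
    pm <- matrix(p, nLevels, nLevels)
    px <- rowSums(pm)
    mu <- sum(seq_len(nLevels) * px)
    s2 <- sum((seq_len(nLevels) - mu)^2 * px)
    if (s2 < 1e-12) { vals <- c(vals, 1); next }  # constant block: convention
    ii <- matrix(seq_len(nLevels), nLevels, nLevels)
    vals <- c(vals, sum((ii - mu) * (t(ii) - mu) * pm) / s2)
  }
  mean(vals)
}

#' Local texture correlation
#'
#' Tiles the image into \code{windowPx} x \code{windowPx} blocks and
#' computes, per block, the gray-level co-occurrence correlation at
#' distance 1 averaged over the four principal directions with 32 gray
#' levels (image scaled to its own min-max range before quantization).
#' Returns the mean over blocks, clamped to [0, 1]. An all-constant block
#' contributes 1 (perfectly predictable texture).
#'
#' @param img an \linkS4class{EnFaceImage} or numeric matrix.
#' @param windowPx block side length in pixels (>= 8; default 32).
#' @return Mean texture correlation in [0, 1].
#' @export
localTextureCorrelation <- function(img, windowPx = 32L) {
  if (is(img, "EnFaceImage")) img <- img@pixels
  if (windowPx < 8L) stop("localTextureCorrelation: windowPx must be >= 8")
  if (nrow(img) < windowPx || ncol(img) < windowPx)
    stop("localTextureCorrelation: image smaller than window")
  nLevels <- 32L
  rng <- range(img)
  q <- if (diff(rng) < 1e-12) matrix(1L, nrow(img), ncol(img))
       else { z <- floor((img - rng[1]) / diff(rng) * nLevels) + 1L
              z[z > nLevels] <- nLevels; z }
  nby <- nrow(img) %/% windowPx; nbx <- ncol(img) %/% windowPx
  vals <- numeric(0)
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    blk <- q[((by - 1) * windowPx + 1):(by * windowPx),
             ((bx - 1) * windowPx + 1):(bx * windowPx)]
    vals <- c(vals, .glcmCorrelation(blk, nLevels))
  }
  min(1, max(0, mean(vals)))
}

#' Peak signal-to-noise ratio
#'
#' PSNR in dB with the peak fixed at 255 (the internal intensity scale):
#' 10 log10(255^2 / MSE). Identical images return \code{Inf}.
#'
#' @param img an \linkS4class{EnFaceImage} or matrix.
#' @param reference image of the same shape (conventionally the five-scan
#'   average).
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnr <- function(img, reference) {
  if (is(img, "EnFaceImage")) img <- img@pixels
  if (is(reference, "EnFaceImage")) reference <- reference@pixels
  if (!identical(dim(img), dim(reference)))
    stop("psnr: images must share dimensions")
  mse <- mean((img - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Quality metrics across cumulative averages
#'
#' Registers the stack to its first scan, forms every cumulative average
#' (n = 1..stack length) and computes the four quality metrics for each;
#' PSNR is referenced to the full-stack average (and is therefore \code{Inf}
#' for the last level).
#'
#' @param stack an \linkS4class{ImageStack} with at least 2 scans.
#' @param cfg a \linkS4class{RegistrationConfig}.
#' @param windowPx texture-correlation window (default 32).
#' @return data.frame with columns nAverage, entropy, std, textureCorr,
#'   psnrDb.
#' @export
qualitySeries <- function(stack, cfg = RegistrationConfig(), windowPx = 32L) {
  stopifnot(is(stack, "ImageStack"))
  N <- nScans(stack)
  if (N < 2L) stop("qualitySeries: stack must contain at least 2 scans")
  regs <- .registerAll(stack, cfg)
  avgs <- lapply(seq_len(N), function(n) .cumulativeAverage(regs, n))
  ref <- avgs[[N]]
  data.frame(
    nAverage = seq_len(N),
    entropy = vapply(avgs, globalEntropy, numeric(1)),
    std = vapply(avgs, globalStd, numeric(1)),
    textureCorr = vapply(avgs, localTextureCorrelation, numeric(1),
                         windowPx = windowPx),
    psnrDb = vapply(avgs, psnr, numeric(1), reference = ref))
}
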