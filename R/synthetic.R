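## Synthetic choriocapillaris phantoms with full ground truth: a
## quasi-periodic capillary mesh with known mean intercapillary spacing,
## multiplicative Gamma speckle, known inter-scan motion and planted
## flow deficits. Every generator is deterministic under a fixed seed.

## default rendering contrasts (gray levels): bright capillary mesh over
## dark septal gaps, with planted deficits darker still so the darkest
## fuzzy cluster isolates them. Kept in the lower half of the [0, 255]
## scale so that heavy multiplicative speckle (looks ~ 2) rarely clips at
## 255; clipping would pile probability mass at the top gray level and
## distort the single-scan histogram statistics.
.VESSEL_GRAY <- 100
.SEPTA_GRAY <- 45
.FD_GRAY <- 10

#' Generate a quasi-periodic CC-like capillary pattern
#'
#' Builds a bright capillary mesh over dark septal gaps from a jittered
#' hexagonal point lattice: the points are the intercapillary (septal)
#' gaps, the tissue between them the capillary network, so the rendered
#' texture is the dense honeycomb of the submacular CC. The lattice row
#' spacing is calibrated so the most prominent band-limited peak of the
#' radially averaged power spectrum falls at 1/\code{icdUm} (within one
#' frequency bin). The \code{"lobular"} variant, emulating the coarser
#' peripheral CC, widens the dark gaps and brightens lobule-centre feeder
#' sites while keeping the same lattice periodicity.
#'
#' @param shapePx integer (h, w) output size in pixels.
#' @param pixelSizeUm pixel size in micrometres (default 10, the 3 mm /
#'   300 px protocol).
#' @param icdUm mean intercapillary distance in micrometres; must be at
#'   least 2 pixels to be resolvable.
#' @param pattern "honeycomb" (default) or "lobular".
#' @param jitter lattice jitter as a fraction of the point spacing, in
#'   [0, 0.5] (default 0.15).
#' @param seed integer seed; same seed, same pattern.
#' @return An \linkS4class{EnFaceImage}.
#' @export
genCCPattern <- function(shapePx, pixelSizeUm = 10, icdUm = 24,
                         pattern = c("honeycomb", "lobular"), jitter = 0.15,
                         seed = 1L) {
  pattern <- match.arg(pattern)
  if (icdUm < 2 * pixelSizeUm)
    stop("genCCPattern: icdUm below the 2-pixel resolvability limit (",
         2 * pixelSizeUm, " um)")
  if (jitter < 0 || jitter > 0.5) stop("genCCPattern: jitter must lie in [0, 0.5]")
  h <- shapePx[1]; w <- shapePx[2]
  set.seed(seed)
  dRow <- icdUm / pixelSizeUm            # lattice row spacing = ICD, px
  a <- dRow * 2 / sqrt(3)                # hexagonal point spacing
  margin <- ceiling(2 * a)
  H <- h + 2 * margin; W <- w + 2 * margin
  rowsY <- seq(1, H, by = dRow)
  pts <- do.call(rbind, lapply(seq_along(rowsY), function(i) {
    xs <- seq(1 + (i %% 2) * a / 2, W, by = a)
    cbind(rowsY[i], xs)
  }))
  pts <- pts + matrix(runif(length(pts), -jitter * a, jitter * a),
                      nrow(pts), 2)
  ## soft septal gap at every lattice point, rendered at subpixel accuracy
  ## (integer rounding would phase-jitter the lattice and wash out the
  ## spectral ring for spacings near the 2-pixel limit)
  sig <- (if (pattern == "honeycomb") 0.28 else 0.40) * dRow
  rad <- ceiling(3 * sig)
  S <- matrix(0, H, W)
  for (i in seq_len(nrow(pts))) {
    cy <- pts[i, 1]; cx <- pts[i, 2]
    ys <- max(1, floor(cy - rad)):min(H, ceiling(cy + rad))
    xs <- max(1, floor(cx - rad)):min(W, ceiling(cx + rad))
    if (!length(ys) || !length(xs)) next
    S[ys, xs] <- S[ys, xs] +
      exp(-(outer((ys - cy)^2, (xs - cx)^2, "+")) / (2 * sig^2))
  }
  S[S > 1] <- 1
  I <- .VESSEL_GRAY - (.VESSEL_GRAY - .SEPTA_GRAY) * S
  if (pattern == "lobular") {
    ## brighten feeder sites at a subset of lobule centres
    nf <- max(1L, nrow(pts) %/% 6L)
    fi <- sample(nrow(pts), nf)
    feeder <- matrix(0, H, W)
    feeder[cbind(pmin(pmax(round(pts[fi, 1]), 1), H),
                 pmin(pmax(round(pts[fi, 2]), 1), W))] <- 1
    feeder <- EBImage::gblur(feeder, sigma = 0.5 * dRow,
                             radius = 2 * ceiling(1.5 * dRow) + 1)
    I <- I + (.VESSEL_GRAY - .SEPTA_GRAY) * feeder / max(feeder)
  }
  I <- I[(margin + 1):(margin + h), (margin + 1):(margin + w)]
  I[I < 0] <- 0; I[I > 255] <- 255
  EnFaceImage(I, pixelSizeUm)
}

#' Apply multiplicative Gamma speckle noise
#'
#' Multiplies every pixel by an independent Gamma(shape = looks, mean = 1)
#' draw and clips to [0, 255]; the standard multi-look surrogate for OCT
#' speckle, with coefficient of variation 1/sqrt(looks). The expected value
#' is preserved before clipping. Deterministic under a fixed seed.
#'
#' @param img an \linkS4class{EnFaceImage}.
#' @param looks Gamma shape (number of looks); lower = noisier.
#' @param seed integer seed.
#' @return The speckled \linkS4class{EnFaceImage}.
#' @export
applySpeckle <- function(img, looks, seed = 1L) {
  stopifnot(is(img, "EnFaceImage"))
  if (looks <= 0) stop("applySpeckle: looks must be positive")
  set.seed(seed)
  p <- img@pixels
  g <- matrix(rgamma(length(p), shape = looks, rate = looks), nrow(p), ncol(p))
  out <- p * g
  out[out > 255] <- 255
  out[out < 0] <- 0
  EnFaceImage(out, img@pixelSizeUm, valid = img@valid)
}

#' Plant dark flow deficits with an exact truth mask
#'
#' Darkens randomly placed, non-overlapping elliptical regions (axis ratio
#' \code{elongation}, areas exponentially distributed around
#' \code{meanSizeUm2}, random orientation) until the planted area fraction
#' is within 10 percent of \code{density}. Returns the modified image and
#' the exact truth mask. Placement failure after the rejection budget
#' (density infeasible for the requested sizes) raises an error.
#'
#' @param img an \linkS4class{EnFaceImage}.
#' @param density target deficit area fraction in (0, 0.5].
#' @param meanSizeUm2 mean deficit area (>= 2 pixel areas).
#' @param elongation major/minor axis ratio (>= 1).
#' @param seed integer seed.
#' @param fdGray gray level the deficit pixels are set to (default 30).
#' @return list(image = \linkS4class{EnFaceImage},
#'   truth = \linkS4class{FDBinaryMap}).
#' @export
plantFDs <- function(img, density, meanSizeUm2, elongation = 1.5, seed = 1L,
                     fdGray = .FD_GRAY) {
  stopifnot(is(img, "EnFaceImage"))
  if (density <= 0 || density > 0.5)
    stop("plantFDs: density must lie in (0, 0.5]")
  ps <- img@pixelSizeUm
  if (meanSizeUm2 < 2 * ps^2)
    stop("plantFDs: meanSizeUm2 must be at least 2 pixel areas")
  if (elongation < 1) stop("plantFDs: elongation must be >= 1")
  set.seed(seed)
  p <- img@pixels
  h <- nrow(p); w <- ncol(p)
  mask <- matrix(FALSE, h, w)
  minAreaPx <- 2
  rejects <- 0L; maxRejects <- 5000L
  frac <- 0
  while (frac < 0.97 * density) {
    if (rejects >= maxRejects)
      stop("plantFDs: placement failed (density too high for deficit size)")
    areaPx <- max(minAreaPx, rexp(1, rate = 1 / (meanSizeUm2 / ps^2)))
    b <- sqrt(areaPx / (pi * elongation))   # semi-minor, px
    aAx <- elongation * b
    th <- runif(1, 0, pi)
    if (2 * aAx + 2 >= min(h, w)) { rejects <- rejects + 1L; next }
    cy <- runif(1, 1 + aAx, h - aAx); cx <- runif(1, 1 + aAx, w - aAx)
    ys <- max(1, floor(cy - aAx - 1)):min(h, ceiling(cy + aAx + 1))
    xs <- max(1, floor(cx - aAx - 1)):min(w, ceiling(cx + aAx + 1))
    Y <- matrix(rep(ys, length(xs)), length(ys)) - cy
    X <- matrix(rep(xs, each = length(ys)), length(ys)) - cx
    u <- cos(th) * Y + sin(th) * X
    v <- -sin(th) * Y + cos(th) * X
    inside <- (u / aAx)^2 + (v / b)^2 <= 1
    if (!any(inside)) { rejects <- rejects + 1L; next }
    sub <- mask[ys, xs]
    if (any(sub & inside)) { rejects <- rejects + 1L; next }     # overlap
    add <- sum(inside) / (h * w)
    if (frac + add > 1.08 * density) { rejects <- rejects + 1L; next }
    sub[inside] <- TRUE
    mask[ys, xs] <- sub
    frac <- frac + add
  }
  p[mask] <- fdGray
  list(image = EnFaceImage(p, ps, valid = img@valid),
       truth = FDBinaryMap(mask, ps, provenance = list(
         planted = TRUE, density = density, meanSizeUm2 = meanSizeUm2,
         elongation = elongation, seed = seed)))
}

#' Build a synthetic CC scene with full ground truth
#'
#' Generates the capillary pattern, plants flow deficits and records the
#' morphometric indices of the exact truth mask (computed through
#' \code{\link{labelFDs}}/\code{\link{fdIndices}} at construction, as a
#' self-check that the truth and the measurement code agree).
#'
#' @param shapePx (h, w) in pixels.
#' @param pixelSizeUm pixel size (default 10 um).
#' @param icdUm mean intercapillary distance (default 24 um, the macular
#'   value).
#' @param pattern "honeycomb" or "lobular".
#' @param jitter lattice jitter fraction (default 0.15).
#' @param fdDensity planted deficit area fraction (default 0.05).
#' @param fdMeanSizeUm2 mean deficit size (default 1500 um^2).
#' @param fdElongation deficit axis ratio (default 1.5).
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticScene}.
#' @export
syntheticScene <- function(shapePx = c(256, 256), pixelSizeUm = 10,
                           icdUm = 24, pattern = "honeycomb", jitter = 0.15,
                           fdDensity = 0.05, fdMeanSizeUm2 = 1500,
                           fdElongation = 1.5, seed = 1L) {
  base <- genCCPattern(shapePx, pixelSizeUm, icdUm, pattern, jitter, seed)
  pl <- plantFDs(base, fdDensity, fdMeanSizeUm2, fdElongation, seed + 1L)
  truthIdx <- fdIndices(labelFDs(pl$truth))
  new("SyntheticScene", cleanImage = pl$image, icdUm = icdUm,
      pattern = pattern, fdTruth = pl$truth, truthIndices = truthIdx,
      seed = as.integer(seed))
}

#' Generate a repeated-scan stack with known motion and speckle
#'
#' Repeat i is the scene's clean image warped by \code{motions[[i]]} and
#' degraded with Gamma speckle (seed + i), emulating repeated volume scans
#' of one location. The first motion must be the identity (the reference
#' scan). Deterministic under fixed seeds.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param motions list of \linkS4class{TransformChain} ground-truth warps,
#'   one per repeat; element 1 must be the identity chain.
#' @param looks speckle looks (lower = noisier; default 2).
#' @param seed integer base seed.
#' @return An \linkS4class{ImageStack}.
#' @export
makeRepeatStack <- function(scene, motions, looks = 2, seed = 1L) {
  stopifnot(is(scene, "SyntheticScene"), length(motions) >= 1L)
  m1 <- motions[[1]]
  if (any(m1@translation != 0) || any(m1@affineMatrix != diag(2)) ||
      length(m1@bsplineDy) && any(m1@bsplineDy != 0))
    stop("makeRepeatStack: motions[[1]] must be the identity")
  imgs <- lapply(seq_along(motions), function(i) {
    warped <- if (i == 1L) scene@cleanImage
              else applyTransform(scene@cleanImage, motions[[i]])
    applySpeckle(warped, looks, seed = seed + i)
  })
  ImageStack(imgs)
}

#' Identity motion chain
#'
#' Convenience constructor for the reference scan's (identity) motion.
#' @return A \linkS4class{TransformChain} representing the identity map.
#' @export
identityChain <- function() TransformChain(translation = c(0, 0))
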