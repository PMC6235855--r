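## Intercapillary distance from the radially averaged 2-D power spectrum.
##
## The quasi-periodic capillary mesh produces a ring in the 2-D power
## spectrum of a CC region; radially averaging turns the ring into a cusp
## whose frequency is the reciprocal of the most prevalent capillary
## spacing — the mean intercapillary distance (ICD).

#' Extract a square physical region of interest
#'
#' Crops the square of side \code{round(sizeUm / pixelSize)} pixels centred
#' at \code{center}; the standard protocol analyses 650 um x 650 um regions
#' with clear CC vasculature (65 px at 10 um/px). The crop must lie fully
#' inside the image.
#'
#' @param img an \linkS4class{EnFaceImage}.
#' @param center integer (row, col) of the ROI centre.
#' @param sizeUm side length in micrometres.
#' @return The cropped \linkS4class{EnFaceImage}.
#' @export
extractROI <- function(img, center, sizeUm) {
  stopifnot(is(img, "EnFaceImage"), sizeUm > 0)
  side <- round(sizeUm / img@pixelSizeUm)
  half <- (side - 1) %/% 2
  r0 <- round(center[1]) - half; c0 <- round(center[2]) - half
  r1 <- r0 + side - 1; c1 <- c0 + side - 1
  if (r0 < 1 || c0 < 1 || r1 > nrow(img@pixels) || c1 > ncol(img@pixels))
    stop(sprintf(
      "extractROI: crop rows %d..%d, cols %d..%d exceeds %d x %d image",
      r0, r1, c0, c1, nrow(img@pixels), ncol(img@pixels)))
  EnFaceImage(img@pixels[r0:r1, c0:c1], img@pixelSizeUm,
              valid = img@valid[r0:r1, c0:c1])
}

#' Radially averaged 2-D power spectrum
#'
#' Subtracts the ROI mean, applies a separable Hann window (suppressing DC
#' leakage that would otherwise mask the cusp at small ROIs), computes the
#' 2-D discrete Fourier transform, and averages the squared magnitude over
#' annular bins one frequency-sample wide. Bin radii are converted to
#' cycles per micrometre through the pixel size.
#'
#' @param roi a square \linkS4class{EnFaceImage} with side >= 32 px.
#' @return A \linkS4class{RadialSpectrum}.
#' @export
radialPowerSpectrum <- function(roi) {
  stopifnot(is(roi, "EnFaceImage"))
  p <- roi@pixels
  n <- nrow(p)
  if (n != ncol(p)) stop("radialPowerSpectrum: ROI must be square")
  if (n < 32) stop("radialPowerSpectrum: ROI side must be >= 32 px")
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  wp <- (p - mean(p)) * outer(hann, hann)
  P <- Mod(fft(wp))^2
  ## integer frequency index of each DFT cell (cycles per ROI side)
  f1 <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  nb <- n %/% 2 - 1L
  bin <- round(fr)
  keep <- bin >= 1 & bin <= nb
  pw <- as.vector(tapply(P[keep], bin[keep], mean))
  freq <- seq_len(nb) / (n * roi@pixelSizeUm)
  new("RadialSpectrum", freqPerUm = freq, power = as.numeric(pw),
      roiSizePx = as.integer(n), pixelSizeUm = roi@pixelSizeUm)
}

## topographic prominence of a local maximum at index i: height above the
## higher of the two key saddles, each the minimum of the stretch running to
## the nearest point at least as high (or to the profile edge; an edge side
## does not bind)
.peakProminence <- function(y, i) {
  n <- length(y)
  leftBase <- -Inf
  if (i > 1) {
    j <- i - 1; m <- y[j]
    while (j > 1 && y[j] < y[i]) { j <- j - 1; m <- min(m, y[j]) }
    leftBase <- m
  }
  rightBase <- -Inf
  if (i < n) {
    j <- i + 1; m <- y[j]
    while (j < n && y[j] < y[i]) { j <- j + 1; m <- min(m, y[j]) }
    rightBase <- m
  }
  base <- max(leftBase, rightBase)
  if (!is.finite(base)) return(0)
  y[i] - base
}

#' Estimate the mean intercapillary distance from a radial spectrum
#'
#' Removes a smooth monotone background from the radial power profile
#' (running-median detrend), then locates the most prominent local maximum
#' within the physiologic search band (default spacings 15-60 um,
#' intersected with the Nyquist limit). The reciprocal of the peak
#' frequency is the ICD. If no local maximum reaches the prominence floor
#' the CC texture is judged unreliable and an error is raised.
#'
#' @param spec a \linkS4class{RadialSpectrum}.
#' @param bandUm numeric (loUm, hiUm) spacing search band in micrometres.
#' @param prominenceFloor minimum detrended peak prominence, as a fraction
#'   of the in-band detrended power range (default 0.05).
#' @return A list with \code{icdUm}, \code{peakFreqPerUm},
#'   \code{peakProminence}.
#' @export
estimateICD <- function(spec, bandUm = c(15, 60), prominenceFloor = 0.05) {
  stopifnot(is(spec, "RadialSpectrum"), length(bandUm) == 2L,
            bandUm[1] < bandUm[2])
  f <- spec@freqPerUm; y <- spec@power
  if (max(y) <= 0) stop("estimateICD: no cusp (empty spectrum)")
  ## detrend in log-power, where the speckle/background slope is smooth
  ly <- log10(y + max(y) * 1e-12)
  k <- min(length(ly) - (1 - length(ly) %% 2), 9L)
  bgl <- stats::runmed(ly, k = max(3, k))
  d <- ly - bgl
  lo <- 1 / bandUm[2]; hi <- min(1 / bandUm[1], 1 / (2 * spec@pixelSizeUm))
  inBand <- which(f >= lo & f <= hi)
  if (length(inBand) < 3) stop("estimateICD: search band outside spectrum support")
  n <- length(d)
  peaks <- inBand[vapply(inBand, function(i) {
    up <- i == 1 || d[i] >= d[i - 1]
    dn <- i == n || d[i] >= d[i + 1]
    strict <- (i > 1 && d[i] > d[i - 1]) || (i < n && d[i] > d[i + 1])
    up && dn && strict
  }, logical(1))]
  if (!length(peaks)) stop("estimateICD: no cusp in the search band")
  prom <- vapply(peaks, function(i) .peakProminence(d, i), numeric(1))
  floorAbs <- prominenceFloor * diff(range(d[inBand]))
  keep <- prom >= floorAbs
  if (!any(keep)) stop("estimateICD: no cusp above the prominence floor")
  best <- peaks[keep][which.max(prom[keep])]
  list(icdUm = 1 / f[best], peakFreqPerUm = f[best],
       peakProminence = max(prom[keep]))
}
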