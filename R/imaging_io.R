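## Raster input/output and illumination normalization.
##
## All images are processed on a real-valued [0, 255] intensity scale
## regardless of the stored bit depth, so the PSNR peak (255) and histogram
## conventions are well defined throughout the pipeline.

.isTiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)
.isPng  <- function(path) grepl("\\.png$",  path, ignore.case = TRUE)

#' Load an en face OCTA image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG raster and attaches the
#' physical pixel size. Intensities are linearly rescaled to real values in
#' [0, 255]. With the standard 3 mm x 3 mm / 300-pixel scanning protocol the
#' pixel size is 10 um/pixel.
#'
#' @param path path to a TIFF or PNG file.
#' @param pixelSizeUm physical pixel size in micrometres (> 0).
#' @return An \linkS4class{EnFaceImage}.
#' @export
loadEnface <- function(path, pixelSizeUm) {
  if (length(pixelSizeUm) != 1L || !is.finite(pixelSizeUm) || pixelSizeUm <= 0)
    stop("loadEnface: pixel size must be a positive number for '", path, "'")
  if (!file.exists(path))
    stop("loadEnface: file not found: '", path, "'")
  raw <- if (.isTiff(path)) {
    tiff::readTIFF(path, all = FALSE)
  } else if (.isPng(path)) {
    png::readPNG(path)
  } else {
    stop("loadEnface: unsupported raster format (need TIFF or PNG): '", path, "'")
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) raw <- raw[, , 1]
    else stop("loadEnface: multi-channel image not supported: '", path, "'")
  }
  if (!is.matrix(raw))
    stop("loadEnface: could not decode a 2-D raster from '", path, "'")
  EnFaceImage(raw * 255, pixelSizeUm = pixelSizeUm)
}

#' Save an image or 2-D map as a lossless raster
#'
#' Writes TIFF (8- or 16-bit) or PNG. Values are mapped linearly from
#' \code{range} onto the full scale of the chosen bit depth, so
#' \code{loadEnface(saveImage(x))} reproduces \code{x} up to quantization of
#' that depth (worst case 255/65535 gray levels at 16 bit).
#'
#' @param img an \linkS4class{EnFaceImage}, logical matrix or numeric matrix.
#' @param path output path (.tif/.tiff or .png).
#' @param bitDepth 8 or 16.
#' @param range numeric length 2; input values mapped to this interval are
#'   written as black..white. Defaults to c(0, 255) (logical masks use 0..1).
#' @return Invisibly, \code{path}.
#' @export
saveImage <- function(img, path, bitDepth = 8, range = NULL) {
  if (is(img, "EnFaceImage")) img <- img@pixels
  if (is.logical(img)) { storage.mode(img) <- "double"; if (is.null(range)) range <- c(0, 1) }
  if (is.null(range)) range <- c(0, 255)
  if (!bitDepth %in% c(8, 16)) stop("saveImage: bitDepth must be 8 or 16")
  v <- (img - range[1]) / (range[2] - range[1])
  v[v < 0] <- 0; v[v > 1] <- 1
  lev <- 2^bitDepth - 1
  v <- round(v * lev) / lev     # symmetric quantization (writers truncate)
  ok <- tryCatch({
    if (.isTiff(path)) {
      tiff::writeTIFF(v, path, bits.per.sample = as.integer(bitDepth))
    } else if (.isPng(path)) {
      png::writePNG(v, path)   # PNG written at 8 bit; use TIFF for 16-bit maps
    } else stop("saveImage: unsupported raster format: '", path, "'")
    TRUE
  }, error = function(e) stop("saveImage: cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Compensate uneven illumination
#'
#' Divides the image by a smooth background field (Gaussian low-pass
#' estimate of the local mean at scale \code{backgroundSigmaUm}), then
#' rescales linearly to [0, 255]. This flattens shading from overlying
#' anatomy (RPE irregularity, floaters, vitreous opacity) while leaving
#' capillary-scale texture untouched, since the background scale is
#' constrained to be much coarser than the capillary spacing.
#'
#' Pixels over an all-black background region (background ~ 0) cannot be
#' normalized; they are set to 0 and reported in a warning rather than an
#' error.
#'
#' @param img an \linkS4class{EnFaceImage}.
#' @param backgroundSigmaUm Gaussian sigma of the background estimate in
#'   micrometres; must be at least 5 pixels worth (default 200 um).
#' @return A normalized \linkS4class{EnFaceImage}.
#' @export
normalizeIllumination <- function(img, backgroundSigmaUm = 200) {
  stopifnot(is(img, "EnFaceImage"))
  ps <- img@pixelSizeUm
  if (backgroundSigmaUm < 5 * ps)
    stop("normalizeIllumination: background sigma must be >= 5 pixels (",
         5 * ps, " um)")
  p <- img@pixels
  if (max(p) <= 0) {
    warning("normalizeIllumination: all-zero image; returning zeros")
    return(EnFaceImage(p, ps, valid = img@valid))
  }
  sigmaPx <- backgroundSigmaUm / ps
  radius <- min(2 * ceiling(3 * sigmaPx) + 1, 2 * (min(dim(p)) %/% 2) - 1)
  ## normalized convolution: zero-pad and renormalize by the smoothed
  ## support mask, so the background estimate is an unbiased local mean
  ## right up to the image border
  num <- EBImage::gblur(p, sigma = sigmaPx, radius = radius, boundary = 0)
  den <- EBImage::gblur(matrix(1, nrow(p), ncol(p)), sigma = sigmaPx,
                        radius = radius, boundary = 0)
  bg <- num / pmax(den, 1e-9)
  eps <- 1e-3 * max(bg)
  dead <- bg <= eps
  r <- p
  r[!dead] <- p[!dead] / bg[!dead]
  r[dead] <- 0
  if (any(dead))
    warning(sprintf("normalizeIllumination: %d pixels over a zero background set to 0",
                    sum(dead)))
  if (max(r) > 0) r <- r / max(r) * 255
  EnFaceImage(r, ps, valid = img@valid)
}
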