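#' @import methods
#' @importFrom stats median quantile rexp runif rgamma optim fft
#' @importFrom utils write.csv
NULL

#' EnFaceImage: a 2-D en face OCTA raster with physical pixel size
#'
#' The basic unit consumed and produced by every stage of the pipeline: a
#' single-channel image of the choriocapillaris slab, held as a numeric
#' matrix on the internal [0, 255] intensity scale, with an isotropic
#' physical pixel size in micrometres. Rows follow the slow-scan (B-scan)
#' axis, columns the fast-scan (A-line) axis; pixel centres sit at integer
#' coordinates (1-based).
#'
#' An optional validity mask marks pixels that carry real signal; pixels
#' mapped from outside the moving image's domain during registration are
#' flagged invalid and excluded from averaging and from mutual-information
#' estimation.
#'
#' @slot pixels numeric matrix of intensities in [0, 255].
#' @slot pixelSizeUm physical size of one pixel in micrometres (> 0).
#' @slot valid logical matrix of the same shape; TRUE where the pixel is
#'   backed by observed data.
#' @export
setClass("EnFaceImage",
  slots = c(pixels = "matrix", pixelSizeUm = "numeric", valid = "matrix"))

setValidity("EnFaceImage", function(object) {
  p <- object@pixels
  if (nrow(p) < 8L || ncol(p) < 8L)
    return("image must be at least 8 x 8 pixels")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (!all(is.finite(p)))
    return("all intensities must be finite")
  if (min(p) < 0)
    return("intensities must be non-negative")
  if (!identical(dim(object@valid), dim(p)))
    return("validity mask must match image dimensions")
  TRUE
})

#' Construct an EnFaceImage
#'
#' @param pixels numeric matrix, intensities in [0, 255].
#' @param pixelSizeUm physical pixel size in micrometres.
#' @param valid optional logical matrix; defaults to all-valid.
#' @return An \linkS4class{EnFaceImage}.
#' @examples
#' img <- EnFaceImage(matrix(128, 16, 16), pixelSizeUm = 10)
#' @export
EnFaceImage <- function(pixels, pixelSizeUm, valid = NULL) {
  storage.mode(pixels) <- "double"
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("EnFaceImage", pixels = pixels, pixelSizeUm = as.numeric(pixelSizeUm),
      valid = valid)
}

#' ImageStack: an ordered series of co-located en face scans
#'
#' Repeated acquisitions of one location, in acquisition order. The first
#' scan is the registration reference. All members share dimensions and
#' pixel size.
#'
#' @slot images list of \linkS4class{EnFaceImage}.
#' @export
setClass("ImageStack", slots = c(images = "list"))

setValidity("ImageStack", function(object) {
  if (length(object@images) < 1L) return("stack must contain at least one image")
  if (!all(vapply(object@images, is, logical(1), class2 = "EnFaceImage")))
    return("all stack members must be EnFaceImage objects")
  d <- lapply(object@images, function(im) dim(im@pixels))
  if (length(unique(d)) != 1L) return("all stack members must share dimensions")
  ps <- vapply(object@images, function(im) im@pixelSizeUm, numeric(1))
  if (length(unique(ps)) != 1L) return("all stack members must share pixel size")
  TRUE
})

#' Construct an ImageStack
#' @param images list of \linkS4class{EnFaceImage} in acquisition order.
#' @return An \linkS4class{ImageStack}.
#' @export
ImageStack <- function(images) new("ImageStack", images = images)

#' TransformChain: parameters of the translation/affine/B-spline cascade
#'
#' The spatial map fitted by the three-step registration, in the resampling
#' convention: it sends fixed-image coordinates to the moving-image
#' coordinates at which the registered value is sampled. The affine part
#' acts about the image centre; the cubic B-spline free-form deformation
#' adds a smooth displacement field parameterised by a regular control
#' lattice. \code{stagewiseCost} records the cost C = -MI (bits) after each
#' fitted stage and is non-increasing by construction.
#'
#' @slot stages character vector of fitted stages, in order.
#' @slot translation numeric (dy, dx) in pixels.
#' @slot affineMatrix 2 x 2 linear matrix (row/col convention).
#' @slot affineOffset numeric (dy, dx) offset in pixels (includes the
#'   translation once the affine stage is fitted).
#' @slot center numeric (cy, cx): fixed point of the affine part.
#' @slot bsplineSpacingPx control-grid spacing in pixels (>= 8).
#' @slot bsplineDy,bsplineDx control-point displacement matrices (pixels).
#' @slot bsplineOrigin numeric (y, x) position of control node (1, 1).
#' @slot stagewiseCost named numeric, cost after each stage.
#' @slot miFloor finite-sample MI bias floor measured from misaligned
#'   probes (bits); reference for the "no-signal" diagnostic.
#' @slot flags character; diagnostic flags such as "no-signal",
#'   "affine-no-gain", "bspline-no-gain", "foldover".
#' @export
setClass("TransformChain",
  slots = c(stages = "character", translation = "numeric",
            affineMatrix = "matrix", affineOffset = "numeric",
            center = "numeric", bsplineSpacingPx = "numeric",
            bsplineDy = "matrix", bsplineDx = "matrix",
            bsplineOrigin = "numeric", stagewiseCost = "numeric",
            miFloor = "numeric", flags = "character"))

setValidity("TransformChain", function(object) {
  if ("affine" %in% object@stages) {
    if (abs(det(object@affineMatrix)) <= 1e-6)
      return("affine matrix must be invertible (|det| > 1e-6)")
  }
  if ("bspline" %in% object@stages) {
    if (object@bsplineSpacingPx < 8)
      return("B-spline grid spacing must be >= 8 pixels")
    if (!identical(dim(object@bsplineDy), dim(object@bsplineDx)))
      return("B-spline displacement lattices must share dimensions")
  }
  if (length(object@stagewiseCost) > 1L &&
      any(diff(object@stagewiseCost) > 1e-9))
    return("stagewise cost must be non-increasing")
  TRUE
})

#' Construct a TransformChain
#'
#' Builds a chain with any subset of stages filled; defaults give the
#' identity map. Used both by the registration routines and to specify
#' ground-truth motion for synthetic stacks.
#'
#' @param translation numeric (dy, dx) pixels.
#' @param affineMatrix 2 x 2 matrix; identity if omitted.
#' @param affineOffset numeric (dy, dx); defaults to \code{translation}
#'   when an affine matrix is supplied.
#' @param center (cy, cx) fixed point of the affine part; required when the
#'   chain is applied unless set later by the registration.
#' @param bsplineSpacingPx,bsplineDy,bsplineDx,bsplineOrigin B-spline stage.
#' @param stagewiseCost,miFloor,flags bookkeeping.
#' @return A \linkS4class{TransformChain}.
#' @export
TransformChain <- function(translation = c(0, 0), affineMatrix = NULL,
                           affineOffset = NULL, center = c(0, 0),
                           bsplineSpacingPx = numeric(0),
                           bsplineDy = NULL, bsplineDx = NULL,
                           bsplineOrigin = c(0, 0),
                           stagewiseCost = numeric(0),
                           miFloor = numeric(0), flags = character(0)) {
  stages <- "translation"
  if (!is.null(affineMatrix)) {
    stages <- c(stages, "affine")
    if (is.null(affineOffset)) affineOffset <- translation
  } else {
    affineMatrix <- diag(2)
    affineOffset <- translation
  }
  if (!is.null(bsplineDy)) {
    stages <- c(stages, "bspline")
  } else {
    bsplineDy <- bsplineDx <- matrix(0, 0, 0)
  }
  new("TransformChain", stages = stages,
      translation = as.numeric(translation), affineMatrix = affineMatrix,
      affineOffset = as.numeric(affineOffset), center = as.numeric(center),
      bsplineSpacingPx = bsplineSpacingPx, bsplineDy = bsplineDy,
      bsplineDx = bsplineDx, bsplineOrigin = as.numeric(bsplineOrigin),
      stagewiseCost = stagewiseCost, miFloor = miFloor, flags = flags)
}

#' RegistrationConfig: hyperparameters of the three-step registration
#'
#' @slot miBins joint-histogram bin count for the mutual-information cost.
#' @slot pyramidLevels multi-resolution levels (coarsest halved repeatedly).
#' @slot maxIterations optimizer iteration budget per stage.
#' @slot maxShiftPx integer search radius of the translation stage.
#' @slot bsplineGridSpacingPx control-grid spacing, pixels (>= 8).
#' @slot bsplineCapFactor displacement cap, in units of the grid spacing.
#' @slot randomSeed seed for any stochastic optimizer component.
#' @slot stages which cascade stages to run.
#' @export
setClass("RegistrationConfig",
  slots = c(miBins = "integer", pyramidLevels = "integer",
            maxIterations = "integer", maxShiftPx = "integer",
            bsplineGridSpacingPx = "numeric", bsplineCapFactor = "numeric",
            randomSeed = "integer", stages = "character"))

setValidity("RegistrationConfig", function(object) {
  if (object@miBins < 8L) return("miBins must be >= 8")
  if (object@pyramidLevels < 1L) return("pyramidLevels must be >= 1")
  if (object@maxIterations < 1L || object@maxShiftPx < 1L)
    return("iteration and search counts must be positive")
  if (object@bsplineGridSpacingPx < 8) return("bsplineGridSpacingPx must be >= 8")
  if (!all(object@stages %in% c("translation", "affine", "bspline")))
    return("stages must be a subset of translation/affine/bspline")
  TRUE
})

#' Construct a RegistrationConfig
#' @param miBins,pyramidLevels,maxIterations,maxShiftPx,bsplineGridSpacingPx
#'   see the class documentation.
#' @param bsplineCapFactor,randomSeed,stages see the class documentation.
#' @return A \linkS4class{RegistrationConfig}.
#' @examples
#' cfg <- RegistrationConfig(stages = c("translation", "affine"))
#' @export
RegistrationConfig <- function(miBins = 32L, pyramidLevels = 3L,
                               maxIterations = 400L, maxShiftPx = 16L,
                               bsplineGridSpacingPx = 32,
                               bsplineCapFactor = 2, randomSeed = 1L,
                               stages = c("translation", "affine", "bspline")) {
  new("RegistrationConfig", miBins = as.integer(miBins),
      pyramidLevels = as.integer(pyramidLevels),
      maxIterations = as.integer(maxIterations),
      maxShiftPx = as.integer(maxShiftPx),
      bsplineGridSpacingPx = as.numeric(bsplineGridSpacingPx),
      bsplineCapFactor = as.numeric(bsplineCapFactor),
      randomSeed = as.integer(randomSeed), stages = stages)
}

#' RadialSpectrum: radially averaged 2-D power spectrum
#'
#' Carrier of the intercapillary-distance "cusp": mean spectral power in
#' annular frequency bins of one frequency-sample width, with the frequency
#' axis in cycles per micrometre.
#'
#' @slot freqPerUm ascending bin-centre frequencies (1/um), ending at or
#'   below the Nyquist frequency 1/(2 * pixel size).
#' @slot power mean power per annulus (arbitrary units, >= 0).
#' @slot roiSizePx side length of the analysed square region.
#' @slot pixelSizeUm pixel size of the analysed region.
#' @export
setClass("RadialSpectrum",
  slots = c(freqPerUm = "numeric", power = "numeric", roiSizePx = "integer",
            pixelSizeUm = "numeric"))

setValidity("RadialSpectrum", function(object) {
  f <- object@freqPerUm
  if (length(f) != length(object@power)) return("frequency/power length mismatch")
  if (length(f) && (f[1] <= 0 || any(diff(f) <= 0)))
    return("frequencies must be strictly increasing and positive")
  if (length(f) && f[length(f)] > 1 / (2 * object@pixelSizeUm) + 1e-12)
    return("frequencies must not exceed Nyquist")
  if (any(object@power < 0)) return("power must be non-negative")
  TRUE
})

#' MembershipMap: fuzzy c-means membership of every pixel
#'
#' Result of fuzzy c-means clustering of pixel intensities: per-pixel
#' membership degrees over k clusters whose centroids are sorted ascending,
#' so cluster 1 is always the darkest ("first membership" = flow deficits).
#'
#' @slot k cluster count.
#' @slot centroids k intensity centroids, strictly increasing.
#' @slot memberships n-pixel x k matrix of degrees (rows sum to 1).
#' @slot hardLabels integer matrix (image shape); argmax membership.
#' @slot explainedVariance between-cluster / total intensity variance of the
#'   hard partition, in [0, 1].
#' @slot objective per-iteration FCM objective values (non-increasing).
#' @slot converged logical.
#' @export
setClass("MembershipMap",
  slots = c(k = "integer", centroids = "numeric", memberships = "matrix",
            hardLabels = "matrix", explainedVariance = "numeric",
            objective = "numeric", converged = "logical"))

setValidity("MembershipMap", function(object) {
  if (object@k >= 2L && any(diff(object@centroids) <= 0))
    return("centroids must be strictly increasing")
  if (ncol(object@memberships) != object@k)
    return("membership columns must equal k")
  rs <- rowSums(object@memberships)
  if (max(abs(rs - 1)) > 1e-6)
    return("membership degrees must sum to 1 per pixel")
  if (!all(object@hardLabels %in% seq_len(object@k)))
    return("hard labels out of range")
  ev <- object@explainedVariance
  if (ev < -1e-9 || ev > 1 + 1e-9) return("explainedVariance must lie in [0, 1]")
  TRUE
})

#' FDBinaryMap: binary flow-deficit map
#'
#' TRUE marks a flow-deficit pixel. Display polarity (FDs drawn black on
#' white or white on black) is a rendering choice; internally TRUE is
#' always "deficit".
#'
#' @slot mask logical matrix.
#' @slot pixelSizeUm pixel size in micrometres.
#' @slot provenance list describing source image and segmentation settings.
#' @export
setClass("FDBinaryMap",
  slots = c(mask = "matrix", pixelSizeUm = "numeric", provenance = "list"))

setValidity("FDBinaryMap", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  TRUE
})

#' Construct an FDBinaryMap
#' @param mask logical matrix (TRUE = flow deficit).
#' @param pixelSizeUm pixel size in micrometres.
#' @param provenance optional list of origin metadata.
#' @return An \linkS4class{FDBinaryMap}.
#' @export
FDBinaryMap <- function(mask, pixelSizeUm, provenance = list()) {
  storage.mode(mask) <- "logical"
  new("FDBinaryMap", mask = mask, pixelSizeUm = as.numeric(pixelSizeUm),
      provenance = provenance)
}

#' FDComponentSet: labelled flow-deficit components with attributes
#'
#' Connected components of an \linkS4class{FDBinaryMap} under 4- or
#' 8-connectivity, each with the geometric attributes that feed the five
#' flow-deficit indices: pixel count, physical area, chain-code perimeter,
#' moments-equivalent ellipse axes and skeleton (medial-axis) length.
#'
#' @slot components data.frame with one row per component: id, nPixels,
#'   areaUm2, perimeterUm, majorAxisUm, minorAxisUm, skeletonLengthUm.
#' @slot pixelIdx list of integer vectors; linear pixel indices per component.
#' @slot contourIdx list of integer vectors; boundary-contour pixel indices.
#' @slot skeletonIdx list of integer vectors; skeleton pixel indices.
#' @slot dim source image dimensions.
#' @slot pixelSizeUm pixel size in micrometres.
#' @slot connectivity 4 or 8.
#' @export
setClass("FDComponentSet",
  slots = c(components = "data.frame", pixelIdx = "list",
            contourIdx = "list", skeletonIdx = "list", dim = "integer",
            pixelSizeUm = "numeric", connectivity = "integer"))

setValidity("FDComponentSet", function(object) {
  n <- nrow(object@components)
  if (length(object@pixelIdx) != n) return("pixelIdx length must match components")
  if (n && !identical(object@components$id, seq_len(n)))
    return("labels must be contiguous from 1")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  TRUE
})

#' SyntheticScene: a CC phantom with full ground truth
#'
#' A synthetic choriocapillaris scene: the noise-free quasi-periodic
#' capillary pattern with known mean intercapillary spacing, planted
#' flow deficits with an exact truth mask, and the morphometric indices of
#' that truth mask (computed at construction through the same morphometrics
#' code path, as a self-check).
#'
#' @slot cleanImage noise-free \linkS4class{EnFaceImage} with FDs planted.
#' @slot icdUm generator mean intercapillary distance (um).
#' @slot pattern "honeycomb" or "lobular".
#' @slot fdTruth \linkS4class{FDBinaryMap} of planted deficits.
#' @slot truthIndices named list: fdd, fdn, fdsUm2, fdari, fdci.
#' @slot seed integer seed the scene was built from.
#' @export
setClass("SyntheticScene",
  slots = c(cleanImage = "EnFaceImage", icdUm = "numeric", pattern = "character",
            fdTruth = "FDBinaryMap", truthIndices = "list", seed = "integer"))

setValidity("SyntheticScene", function(object) {
  if (!identical(dim(object@fdTruth@mask), dim(object@cleanImage@pixels)))
    return("truth mask must match clean image shape")
  if (!object@pattern %in% c("honeycomb", "lobular"))
    return("pattern must be honeycomb or lobular")
  TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn EnFaceImage pixel matrix accessor
#' @param object an object of the documented class.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @export
setMethod("pixels", "EnFaceImage", function(object) object@pixels)

#' @describeIn EnFaceImage physical pixel size (um) accessor
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @export
setMethod("pixelSize", "EnFaceImage", function(object) object@pixelSizeUm)
#' @export
setMethod("pixelSize", "FDBinaryMap", function(object) object@pixelSizeUm)

#' @describeIn EnFaceImage validity-mask accessor
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @export
setMethod("validMask", "EnFaceImage", function(object) object@valid)

#' @describeIn ImageStack number of scans
#' @param object an ImageStack.
#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))
#' @export
setMethod("nScans", "ImageStack", function(object) length(object@images))

#' @describeIn ImageStack extract one scan
#' @param x an ImageStack.
#' @param i scan index.
#' @export
setMethod("[[", "ImageStack", function(x, i) x@images[[i]])

#' @describeIn FDBinaryMap logical mask accessor
#' @export
setGeneric("fdMask", function(object) standardGeneric("fdMask"))
#' @export
setMethod("fdMask", "FDBinaryMap", function(object) object@mask)

#' @describeIn FDComponentSet per-component attribute table
#' @export
setGeneric("fdComponents", function(object) standardGeneric("fdComponents"))
#' @export
setMethod("fdComponents", "FDComponentSet", function(object) object@components)

#' @describeIn FDComponentSet number of components
#' @param x an FDComponentSet.
#' @export
setMethod("length", "FDComponentSet", function(x) nrow(x@components))

#' @describeIn MembershipMap sorted cluster centroids
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @export
setMethod("centroids", "MembershipMap", function(object) object@centroids)

#' @describeIn MembershipMap hard-label matrix
#' @export
setGeneric("hardLabels", function(object) standardGeneric("hardLabels"))
#' @export
setMethod("hardLabels", "MembershipMap", function(object) object@hardLabels)

## ---- show methods ----------------------------------------------------------

setMethod("show", "EnFaceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("EnFaceImage %d x %d px (%.0f x %.0f um), %.3g um/px\n",
              d[1], d[2], d[1] * object@pixelSizeUm, d[2] * object@pixelSizeUm,
              object@pixelSizeUm))
  cat(sprintf("  intensity range [%.1f, %.1f], %d invalid px\n",
              min(object@pixels), max(object@pixels), sum(!object@valid)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@images[[1]]@pixels)
  cat(sprintf("ImageStack of %d scans, %d x %d px, %.3g um/px\n",
              length(object@images), d[1], d[2], object@images[[1]]@pixelSizeUm))
})

setMethod("show", "TransformChain", function(object) {
  cat("TransformChain stages:", paste(object@stages, collapse = " -> "), "\n")
  cat(sprintf("  translation (dy, dx) = (%.3f, %.3f) px\n",
              object@translation[1], object@translation[2]))
  if ("affine" %in% object@stages) {
    cat("  affine matrix:\n")
    print(round(object@affineMatrix, 4))
    cat(sprintf("  offset (dy, dx) = (%.3f, %.3f) px\n",
                object@affineOffset[1], object@affineOffset[2]))
  }
  if ("bspline" %in% object@stages)
    cat(sprintf("  B-spline grid %d x %d nodes, spacing %.0f px, max |disp| %.2f px\n",
                nrow(object@bsplineDy), ncol(object@bsplineDy),
                object@bsplineSpacingPx,
                max(abs(c(object@bsplineDy, object@bsplineDx)), 0)))
  if (length(object@stagewiseCost))
    cat("  cost (-MI bits):",
        paste(sprintf("%s=%.4f", names(object@stagewiseCost),
                      object@stagewiseCost), collapse = ", "), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "RadialSpectrum", function(object) {
  cat(sprintf("RadialSpectrum: %d bins over [%.4g, %.4g] 1/um (ROI %d px)\n",
              length(object@freqPerUm), object@freqPerUm[1],
              object@freqPerUm[length(object@freqPerUm)], object@roiSizePx))
})

setMethod("show", "MembershipMap", function(object) {
  cat(sprintf("MembershipMap: k = %d, centroids %s, explained variance %.4f\n",
              object@k, paste(sprintf("%.1f", object@centroids), collapse = "/"),
              object@explainedVariance))
})

setMethod("show", "FDBinaryMap", function(object) {
  cat(sprintf("FDBinaryMap %d x %d px, FD fraction %.4f, %.3g um/px\n",
              nrow(object@mask), ncol(object@mask), mean(object@mask),
              object@pixelSizeUm))
})

setMethod("show", "FDComponentSet", function(object) {
  cat(sprintf("FDComponentSet: %d components (connectivity %d)\n",
              nrow(object@components), object@connectivity))
  if (nrow(object@components))
    cat(sprintf("  total area %.0f um2, mean size %.1f um2\n",
                sum(object@components$areaUm2), mean(object@components$areaUm2)))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene (%s), ICD %.1f um, planted FDD %.4f, seed %d\n",
              object@pattern, object@icdUm, mean(object@fdTruth@mask),
              object@seed))
})
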