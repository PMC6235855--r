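## Flow-deficit morphometrics: connected-component labelling with geometric
## attributes, the five quantitative indices (FDD, FDN, FDS, FDARI, FDCI)
## and the six functional maps.
##
## Attribute conventions (all scaled by the physical pixel size):
##  - area: pixel count x pixelSize^2
##  - perimeter: 8-connected boundary chain length, unit steps 1 and
##    diagonal steps sqrt(2); an isolated pixel counts 4 pixel-units. This
##    estimator keeps the complexity index of large disks near 1 (the
##    isoperimetric normalization of FDCI); pure pixel-edge counting would
##    bias disks to ~1.27.
##  - axes: moments-equivalent ellipse (second central moments with the
##    1/12 pixel-spread correction); a single pixel gets major = minor =
##    one pixel.
##  - skeleton length: total branch length of the medial axis obtained by
##    Zhang-Suen thinning (spanning-tree length of the 8-adjacent skeleton
##    pixels).

## zero-padded shift of a 0/1 matrix by (dy, dx)
.shiftMat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

## Zhang-Suen morphological thinning to a 1-px skeleton
.thinMask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- .shiftMat(m, 1, 0);  p3 <- .shiftMat(m, 1, -1)
      p4 <- .shiftMat(m, 0, -1); p5 <- .shiftMat(m, -1, -1)
      p6 <- .shiftMat(m, -1, 0); p7 <- .shiftMat(m, -1, 1)
      p8 <- .shiftMat(m, 0, 1);  p9 <- .shiftMat(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

## chain length of one ocontour polygon (closed), in pixel units
.chainLength <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(4)        # isolated pixel: its full boundary
  d <- pts[c(2:n, 1), , drop = FALSE] - pts
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

## connected components of a logical mask via the pixel-adjacency graph
.labelComponents <- function(mask, connectivity) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(list())
  id <- matrix(0L, h, w); id[idx] <- seq_len(n)
  pairs <- function(dy, dx) {
    ys <- seq_len(h - dy)
    xs <- if (dx >= 0) seq_len(w - dx) else (1 - dx):w
    a <- id[ys, xs, drop = FALSE]
    b <- id[ys + dy, xs + dx, drop = FALSE]
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  el <- rbind(pairs(0, 1), pairs(1, 0))
  if (connectivity == 8L) el <- rbind(el, pairs(1, 1), pairs(1, -1))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  ## relabel in order of first pixel occurrence so labels are deterministic
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  split(idx, relab[memb])
}

#' Label flow-deficit components and measure their geometry
#'
#' Finds the connected components of a binary flow-deficit map under 4- or
#' 8-connectivity (default 8: diagonally touching deficit pixels read as
#' one deficit) and computes per-component area, boundary perimeter,
#' moments-equivalent ellipse axes and skeleton length. An empty mask
#' yields an empty set.
#'
#' @param fd an \linkS4class{FDBinaryMap}.
#' @param connectivity 4 or 8 (default 8).
#' @return An \linkS4class{FDComponentSet}.
#' @export
labelFDs <- function(fd, connectivity = 8L) {
  stopifnot(is(fd, "FDBinaryMap"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("labelFDs: connectivity must be 4 or 8")
  mask <- fd@mask
  h <- nrow(mask); w <- ncol(mask)
  ps <- fd@pixelSizeUm
  groups <- .labelComponents(mask, connectivity)
  nComp <- length(groups)
  emptyDf <- data.frame(id = integer(0), nPixels = integer(0),
                        areaUm2 = numeric(0), perimeterUm = numeric(0),
                        majorAxisUm = numeric(0), minorAxisUm = numeric(0),
                        skeletonLengthUm = numeric(0))
  if (nComp == 0L)
    return(new("FDComponentSet", components = emptyDf, pixelIdx = list(),
               contourIdx = list(), skeletonIdx = list(),
               dim = c(h, w), pixelSizeUm = ps, connectivity = connectivity))

  lab <- matrix(0L, h, w)
  for (i in seq_len(nComp)) lab[groups[[i]]] <- i
  contours <- EBImage::ocontour(lab)
  skel <- .thinMask(mask)

  rows <- ((seq_len(h * w) - 1L) %% h) + 1L   # row of each linear index
  cols <- ((seq_len(h * w) - 1L) %/% h) + 1L

  comp <- emptyDf
  contourIdx <- skeletonIdx <- vector("list", nComp)
  for (i in seq_len(nComp)) {
    idx <- groups[[i]]
    nPix <- length(idx)
    r <- rows[idx]; cc <- cols[idx]
    ## contour: ocontour returns 0-based (dim1, dim2) vertex coordinates
    pts <- contours[[i]]
    perimPx <- .chainLength(pts)
    contourIdx[[i]] <- unique(pts[, 2] * h + pts[, 1] + 1L)
    if (nPix == 1L) {
      majorPx <- minorPx <- 1
    } else {
      uyy <- mean((r - mean(r))^2) + 1 / 12
      uxx <- mean((cc - mean(cc))^2) + 1 / 12
      uxy <- mean((r - mean(r)) * (cc - mean(cc)))
      common <- sqrt((uyy - uxx)^2 + 4 * uxy^2)
      majorPx <- 2 * sqrt(2) * sqrt(uyy + uxx + common)
      minorPx <- 2 * sqrt(2) * sqrt(pmax(uyy + uxx - common, 1e-12))
    }
    sIdx <- idx[skel[idx]]
    skeletonIdx[[i]] <- sIdx
    comp <- rbind(comp, data.frame(
      id = i, nPixels = nPix, areaUm2 = nPix * ps^2,
      perimeterUm = perimPx * ps, majorAxisUm = majorPx * ps,
      minorAxisUm = minorPx * ps,
      skeletonLengthUm = .skeletonLength(sIdx, h) * ps))
  }
  new("FDComponentSet", components = comp, pixelIdx = groups,
      contourIdx = contourIdx, skeletonIdx = skeletonIdx,
      dim = c(h, w), pixelSizeUm = ps, connectivity = connectivity)
}

## total branch length of a set of skeleton pixels: spanning-tree length of
## their 8-adjacency graph (unit and sqrt(2) steps)
.skeletonLength <- function(idx, h) {
  n <- length(idx)
  if (n <= 1L) return(0)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  el <- NULL; wts <- NULL
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    key <- paste(r + o[1], cc + o[2])
    m <- match(key, paste(r, cc))
    keep <- !is.na(m)
    if (any(keep)) {
      el <- rbind(el, cbind(which(keep), m[keep]))
      wts <- c(wts, rep(sqrt(o[1]^2 + o[2]^2), sum(keep)))
    }
  }
  if (is.null(el)) return(0)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- wts
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  mst <- igraph::mst(g)
  sum(igraph::E(mst)$weight)
}

#' Flow-deficit density (FDD)
#'
#' Ratio of the image area occupied by flow deficits to the total image
#' area: deficit-pixel count over total pixel count, in [0, 1].
#'
#' @param fd an \linkS4class{FDBinaryMap}.
#' @return FDD in [0, 1].
#' @export
computeFDD <- function(fd) {
  stopifnot(is(fd, "FDBinaryMap"))
  mean(fd@mask)
}

#' Flow-deficit aspect-ratio index (FDARI)
#'
#' Mean over components of major-axis length over minor-axis length of the
#' moments-equivalent ellipse; always >= 1. Captures elongation and
#' acircularity of the deficits.
#'
#' @param c an \linkS4class{FDComponentSet} with at least one component.
#' @return FDARI (>= 1, up to discretization).
#' @export
computeFDARI <- function(c) {
  stopifnot(is(c, "FDComponentSet"))
  if (length(c) == 0L) stop("computeFDARI: undefined on an empty component set")
  mean(c@components$majorAxisUm / c@components$minorAxisUm)
}

#' Flow-deficit complexity index (FDCI)
#'
#' Mean over components of P^2 / (4 pi A), the isoperimetric quotient of
#' each deficit (P and A in consistent physical units, so the index is
#' dimensionless). A disk scores ~1; boundary roughness raises the value.
#'
#' @param c an \linkS4class{FDComponentSet} with at least one component.
#' @return FDCI.
#' @export
computeFDCI <- function(c) {
  stopifnot(is(c, "FDComponentSet"))
  if (length(c) == 0L) stop("computeFDCI: undefined on an empty component set")
  mean(c@components$perimeterUm^2 / (4 * pi * c@components$areaUm2))
}

#' Flow-deficit number and mean size (FDN, FDS)
#'
#' FDN is the component count; FDS the mean component area in um^2. An
#' empty set reports FDS = 0 with \code{empty = TRUE}.
#'
#' @param c an \linkS4class{FDComponentSet}.
#' @return list(fdn, fdsUm2, empty).
#' @export
computeFDNFDS <- function(c) {
  stopifnot(is(c, "FDComponentSet"))
  n <- length(c)
  if (n == 0L) return(list(fdn = 0L, fdsUm2 = 0, empty = TRUE))
  list(fdn = n, fdsUm2 = sum(c@components$areaUm2) / n, empty = FALSE)
}

#' All five flow-deficit indices
#'
#' Convenience wrapper returning FDD, FDN, FDS, FDARI and FDCI of a
#' component set in one named list (FDARI and FDCI are NA on an empty set).
#'
#' @param c an \linkS4class{FDComponentSet}.
#' @return list(fdd, fdn, fdsUm2, fdari, fdci).
#' @export
fdIndices <- function(c) {
  stopifnot(is(c, "FDComponentSet"))
  nf <- computeFDNFDS(c)
  list(fdd = sum(c@components$nPixels) / prod(c@dim),
       fdn = nf$fdn, fdsUm2 = nf$fdsUm2,
       fdari = if (nf$empty) NA_real_ else computeFDARI(c),
       fdci = if (nf$empty) NA_real_ else computeFDCI(c))
}

#' Generate the six flow-deficit functional maps
#'
#' Builds the binary map, the boundary (perimeter) map, the skeleton
#' (centre-length) map, and the three per-component scalar maps where every
#' pixel of a deficit carries that deficit's aspect ratio, complexity term
#' or area (um^2); zero elsewhere.
#'
#' @param c an \linkS4class{FDComponentSet}.
#' @return list of matrices: binary, perimeter, length, aspectRatio,
#'   complexity, size.
#' @export
generateFDMaps <- function(c) {
  stopifnot(is(c, "FDComponentSet"))
  h <- c@dim[1]; w <- c@dim[2]
  binary <- matrix(FALSE, h, w)
  perim <- matrix(FALSE, h, w)
  len <- matrix(FALSE, h, w)
  ar <- cx <- sz <- matrix(0, h, w)
  df <- c@components
  for (i in seq_len(length(c))) {
    idx <- c@pixelIdx[[i]]
    binary[idx] <- TRUE
    perim[c@contourIdx[[i]]] <- TRUE
    len[c@skeletonIdx[[i]]] <- TRUE
    ar[idx] <- df$majorAxisUm[i] / df$minorAxisUm[i]
    cx[idx] <- df$perimeterUm[i]^2 / (4 * pi * df$areaUm2[i])
    sz[idx] <- df$areaUm2[i]
  }
  list(binary = binary, perimeter = perim, length = len,
       aspectRatio = ar, complexity = cx, size = sz)
}
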