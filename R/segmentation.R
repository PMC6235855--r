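## Fuzzy c-means segmentation of the averaged CC image into intensity
## clusters, elbow selection of the cluster count, extraction of the binary
## flow-deficit map (the darkest cluster) and mask-based removal of retinal
## projection artifacts.

## explained variance of a hard partition of intensities x into labels
.explainedVariance <- function(x, labels) {
  tot <- sum((x - mean(x))^2)
  if (tot <= 0) return(1)
  means <- tapply(x, labels, mean)
  n <- tabulate(labels)
  between <- sum(n[n > 0] * (means - mean(x))^2)
  min(1, max(0, between / tot))
}

#' Fuzzy c-means clustering of pixel intensities
#'
#' Standard FCM on the one-dimensional pixel-intensity feature: alternating
#' membership and centroid updates until the maximum membership change
#' drops below \code{tol} or \code{maxIter} is reached. The objective
#' sum(u^m d^2) is non-increasing across iterations. Centroids are returned
#' sorted ascending with memberships permuted to match, so cluster 1 is
#' always the darkest. Centroids are initialized at evenly spaced intensity
#' quantiles (deterministic); an empty cluster is re-seeded once from a
#' seeded uniform draw over the intensity range, and a recurrence raises a
#' convergence error.
#'
#' @param img an \linkS4class{EnFaceImage} or numeric matrix.
#' @param k cluster count (>= 1).
#' @param fuzzifier membership exponent m > 1 (default 2).
#' @param tol convergence tolerance on membership change (default 1e-5).
#' @param maxIter iteration cap (default 300).
#' @param seed seed for the empty-cluster re-initialization draw.
#' @return A \linkS4class{MembershipMap}.
#' @export
fcmCluster <- function(img, k, fuzzifier = 2, tol = 1e-5, maxIter = 300L,
                       seed = 1L) {
  p <- if (is(img, "EnFaceImage")) img@pixels else img
  if (k < 1L) stop("fcmCluster: k must be >= 1")
  if (fuzzifier <= 1) stop("fcmCluster: fuzzifier must be > 1")
  if (tol <= 0) stop("fcmCluster: tol must be > 0")
  x <- as.vector(p)
  n <- length(x)
  if (k == 1L) {
    u <- matrix(1, n, 1)
    return(new("MembershipMap", k = 1L, centroids = mean(x), memberships = u,
               hardLabels = matrix(1L, nrow(p), ncol(p)),
               explainedVariance = 1,
               objective = sum((x - mean(x))^2), converged = TRUE))
  }
  ctr <- as.numeric(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k)))
  ## guard identical quantiles on near-constant images
  if (any(diff(ctr) <= 0)) ctr <- ctr + seq_len(k) * 1e-9
  uPrev <- NULL
  objTrace <- numeric(0)
  converged <- FALSE
  reseeded <- FALSE
  rngState <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- outer(x, ctr, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-12)
    ## membership: u_ik = 1 / sum_l (d_ik/d_il)^(2/(m-1))
    inv <- d2^(-1 / (fuzzifier - 1))
    u <- inv / rowSums(inv)
    um <- u^fuzzifier
    objTrace <- c(objTrace, sum(um * d2))
    colw <- colSums(um)
    if (any(colw < 1e-9)) {               # centroid collapse
      if (reseeded) stop("fcmCluster: empty cluster recurred; not converged")
      reseeded <- TRUE
      set.seed(seed)
      ctr[colw < 1e-9] <- runif(sum(colw < 1e-9), min(x), max(x))
      next
    }
    ctr <- colSums(um * x) / colw
    if (!is.null(uPrev) && max(abs(u - uPrev)) < tol) { converged <- TRUE; break }
    uPrev <- u
  }
  ord <- order(ctr)
  ctr <- ctr[ord]
  if (any(diff(ctr) <= 0)) ctr <- ctr + cumsum(c(0, diff(ctr) <= 0)) * 1e-9
  u <- u[, ord, drop = FALSE]
  hard <- max.col(u, ties.method = "first")
  new("MembershipMap", k = as.integer(k), centroids = ctr, memberships = u,
      hardLabels = matrix(as.integer(hard), nrow(p), ncol(p)),
      explainedVariance = .explainedVariance(x, hard),
      objective = objTrace, converged = converged)
}

#' Elbow selection of the cluster count
#'
#' Increases the number of fuzzy clusters until the between-cluster
#' variance of the hard partition explains at least \code{threshold} of the
#' total intensity variance (the 99 percent rule), returning the smallest
#' such k. If no k up to \code{kMax} reaches the threshold, \code{kMax} is
#' returned with a warning. A constant image (zero total variance) returns
#' k = 1 with a warning.
#'
#' @param img an \linkS4class{EnFaceImage} or numeric matrix.
#' @param kMax largest cluster count to try (2..10; default 8).
#' @param threshold explained-variance target in (0, 1) (default 0.99).
#' @param ... passed to \code{\link{fcmCluster}}.
#' @return The selected integer k (attribute \code{"explainedVariance"}
#'   carries the achieved value).
#' @export
elbowSelectK <- function(img, kMax = 8L, threshold = 0.99, ...) {
  p <- if (is(img, "EnFaceImage")) img@pixels else img
  if (kMax < 2L || kMax > 10L) stop("elbowSelectK: kMax must lie in 2..10")
  if (threshold <= 0 || threshold >= 1)
    stop("elbowSelectK: threshold must lie in (0, 1)")
  if (sum((p - mean(p))^2) <= 0) {
    warning("elbowSelectK: constant image; returning k = 1")
    return(structure(1L, explainedVariance = 1))
  }
  ev <- NA_real_
  for (k in 2:kMax) {
    m <- fcmCluster(p, k, ...)
    ev <- m@explainedVariance
    if (ev >= threshold) return(structure(as.integer(k), explainedVariance = ev))
  }
  warning(sprintf(
    "elbowSelectK: threshold %.3f not reached by k <= %d (best %.4f)",
    threshold, kMax, ev))
  structure(as.integer(kMax), explainedVariance = ev)
}

#' Extract the binary flow-deficit map
#'
#' The flow-deficit map is the "first membership": all pixels whose hard
#' label is the cluster with the lowest centroid (flow deficits are the
#' darkest structures in en face CC OCTA).
#'
#' @param m a \linkS4class{MembershipMap} with k >= 2.
#' @param pixelSizeUm physical pixel size to attach to the map.
#' @return An \linkS4class{FDBinaryMap} (TRUE = flow deficit).
#' @export
extractFDMap <- function(m, pixelSizeUm) {
  stopifnot(is(m, "MembershipMap"))
  if (m@k < 2L)
    stop("extractFDMap: k must be >= 2 (no deficit/vasculature separation)")
  FDBinaryMap(m@hardLabels == 1L, pixelSizeUm,
              provenance = list(k = m@k, centroids = m@centroids,
                                explainedVariance = m@explainedVariance))
}

#' Remove retinal projection artifacts from a flow-deficit map
#'
#' Flow signal of large retinal vessels projects onto the CC slab and can
#' carve spurious deficits. Given a caller-supplied binary retinal-vessel
#' mask, every connected FD component whose fraction of pixels under the
#' vessel mask is at least \code{overlapFrac} is removed. An empty vessel
#' mask leaves the map unchanged; \code{overlapFrac = 0} removes every
#' component touching the mask.
#'
#' @param fd an \linkS4class{FDBinaryMap}.
#' @param vesselMask logical matrix of the same shape (TRUE = retinal
#'   vessel).
#' @param overlapFrac removal threshold in [0, 1] (default 0.5).
#' @param connectivity 4 or 8 (default 8).
#' @return The cleaned \linkS4class{FDBinaryMap}.
#' @export
removeProjectionArtifacts <- function(fd, vesselMask, overlapFrac = 0.5,
                                      connectivity = 8L) {
  stopifnot(is(fd, "FDBinaryMap"))
  if (!identical(dim(vesselMask), dim(fd@mask)))
    stop("removeProjectionArtifacts: vessel mask shape mismatch")
  if (overlapFrac < 0 || overlapFrac > 1)
    stop("removeProjectionArtifacts: overlapFrac must lie in [0, 1]")
  if (!any(vesselMask)) return(fd)
  comps <- labelFDs(fd, connectivity = connectivity)
  mask <- fd@mask
  for (i in seq_along(comps@pixelIdx)) {
    idx <- comps@pixelIdx[[i]]
    frac <- mean(vesselMask[idx])
    drop <- if (overlapFrac == 0) frac > 0 else frac >= overlapFrac
    if (drop) mask[idx] <- FALSE
  }
  FDBinaryMap(mask, fd@pixelSizeUm,
              provenance = c(fd@provenance,
                             list(projectionArtifactOverlapFrac = overlapFrac)))
}
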