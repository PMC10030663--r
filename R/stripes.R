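## Stripe (bulk-motion artifact) detection and vesselness segmentation of
## en-face angiography images.

#' Robust per-position stripe statistic
#'
#' Bulk-motion-corrupted B-scans decorrelate as a whole, which raises the
#' speckle-variance level of the entire slow-axis position. The per-position
#' level is summarized by the lower quartile across the fast axis - robust
#' both to speckle and to bright vasculature covering part of the B-scan -
#' and the statistic is its robust z-score against a slow-axis
#' running-median trend.
#'
#' The residual scale is floored at a fraction of the background level
#' (default 5%), because stripe artifacts are large-amplitude events and a
#' MAD estimated from nearly noise-free data would otherwise flag benign
#' fluctuations.
#'
#' @param mip en-face angiography MIP, matrix (x, y) with y the slow axis.
#' @param trendWindow odd window of the running-median trend (default about
#'   a quarter of the slow axis).
#' @param floorFrac scale floor as a fraction of the median background
#'   level.
#' @return numeric vector of z-scores, one per slow-axis position.
#' @export
stripeZScores <- function(mip, trendWindow = NULL, floorFrac = 0.05) {
  s <- apply(mip, 2, quantile, probs = 0.25, names = FALSE)
  ny <- length(s)
  k <- if (is.null(trendWindow)) max(5L, 2L * (ny %/% 8L) + 1L) else trendWindow
  k <- min(k, if (ny %% 2L == 1L) ny else ny - 1L)
  ## mirror-pad so the running median is unbiased at the slow-axis ends
  h <- k %/% 2L
  sp <- c(rev(s[seq_len(h)]), s, rev(s[(ny - h + 1L):ny]))
  trend <- runmed(sp, k)[(h + 1L):(h + ny)]
  resid <- s - trend
  sigma <- max(mad(resid), floorFrac * median(s), 1e-12)
  as.numeric(resid / sigma)
}

#' Detect stripe-like bulk-motion artifact bands
#'
#' Flags slow-axis positions whose \code{\link{stripeZScores}} statistic
#' exceeds \code{zThreshold} and groups consecutive flagged positions into
#' disjoint half-open bands. An empty mask on clean input is the expected
#' result, not an error.
#'
#' @param x an \linkS4class{OCAVolume} (projected over depth) or an en-face
#'   MIP matrix (x, y).
#' @param sensitivity list: zThreshold (robust z-score cut, default 6),
#'   trendWindow (passed to \code{stripeZScores}).
#' @return a \linkS4class{StripeMask} (bands 0-based, half-open).
#' @export
detectStripes <- function(x, sensitivity = list()) {
  se <- modifyList(list(zThreshold = 6, trendWindow = NULL,
                        floorFrac = 0.05), sensitivity)
  mip <- if (is(x, "OCAVolume")) mipProject(x) else x
  if (any(!is.finite(mip))) stop("input must be finite")
  z <- stripeZScores(mip, se$trendWindow, se$floorFrac)
  flag <- z > se$zThreshold
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  bands <- cbind(start = starts[on] - 1L, end = ends[on])
  scores <- vapply(on, function(i) max(z[starts[i]:ends[i]]), 1)
  stripeMask(bands = bands, scores = scores, nSlow = ncol(mip))
}

fibonacciSphere <- function(K) {
  i <- seq_len(K) - 0.5
  phi <- acos(1 - 2 * i / K)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(phi), sin(phi) * cos(theta), sin(phi) * sin(theta))
}

#' Optimally oriented flux vesselness
#'
#' For each scale rho the oriented-flux matrix at a voxel is the outward
#' flux of the (Gaussian-regularized) image gradient through the sphere (or
#' circle in 2D) of radius rho, assembled from gradient samples at
#' rho-offset points; its eigenvalues measure inward flux across the tube
#' cross-section. The bright-tube response is the rectified mean of the
#' cross-sectional (most negative) eigenvalues, maximized over scales; the
#' surface average makes responses comparable across scales.
#'
#' @param image 2D matrix or 3D array of intensities.
#' @param radii positive scale set, pixels.
#' @param sigma Gaussian regularization of the gradient, pixels.
#' @return list: response (rectified, >= 0) and scale (argmax radius) maps.
#' @export
oofVesselness <- function(image, radii = c(2, 3, 4), sigma = 1) {
  if (!length(radii) || any(radii <= 0)) stop("radii must be positive")
  d <- dim(image)
  if (any(radii > min(d) / 2)) stop("radii exceed half the image extent")
  is3d <- length(d) == 3L
  d3 <- if (is3d) d else c(d, 1L)
  g <- gaussSmooth(array(as.numeric(image), d3), sigma)
  dk <- c(-0.5, 0, 0.5)
  g1 <- .convAxis(g, d3, dk, 0L)
  g2 <- .convAxis(g, d3, dk, 1L)
  g3 <- if (is3d) .convAxis(g, d3, dk, 2L) else array(0, d3)
  resp <- array(0, d3)
  smap <- array(radii[1], d3)
  for (rho in radii) {
    if (is3d) {
      K <- max(26L, min(round(4 * pi * rho^2), 96L))
      nrm <- fibonacciSphere(K)
    } else {
      K <- max(8L, ceiling(2 * pi * rho))
      ang <- 2 * pi * (seq_len(K) - 1) / K
      nrm <- cbind(cos(ang), sin(ang), 0)
    }
    q11 <- q22 <- q33 <- q12 <- q13 <- q23 <- array(0, d3)
    for (k in seq_len(K)) {
      n <- nrm[k, ]
      s1 <- .shiftSample(g1, d3, rho * n[1], rho * n[2], rho * n[3])
      s2 <- .shiftSample(g2, d3, rho * n[1], rho * n[2], rho * n[3])
      q11 <- q11 + s1 * n[1]
      q22 <- q22 + s2 * n[2]
      q12 <- q12 + 0.5 * (s1 * n[2] + s2 * n[1])
      if (is3d) {
        s3 <- .shiftSample(g3, d3, rho * n[1], rho * n[2], rho * n[3])
        q33 <- q33 + s3 * n[3]
        q13 <- q13 + 0.5 * (s1 * n[3] + s3 * n[1])
        q23 <- q23 + 0.5 * (s2 * n[3] + s3 * n[2])
      }
    }
    if (is3d) {
      ev <- .sym3Eigen(q11 / K, q22 / K, q33 / K, q12 / K, q13 / K, q23 / K)
      ## cross-sectional eigenvalues = the two of larger magnitude
      r <- pmax(0, -(ev$l2 + ev$l3) / 2)
    } else {
      a <- q11 / K; b <- q22 / K; c2 <- q12 / K
      disc <- sqrt(((a - b) / 2)^2 + c2^2)
      lmin <- (a + b) / 2 - disc
      r <- pmax(0, -lmin)
    }
    r <- array(r, d3)
    better <- r > resp
    resp[better] <- r[better]
    smap[better] <- rho
  }
  if (!is3d) {
    dim(resp) <- d
    dim(smap) <- d
  }
  list(response = resp, scale = smap)
}

#' Binarize a vesselness map
#'
#' Hysteresis thresholding: voxels above the high quantile of the positive
#' responses seed the mask, connected regions above the low quantile are
#' kept, and objects smaller than \code{minSize} voxels are removed. A
#' degenerate (all-equal) map yields an empty mask with a warning.
#'
#' @param vesselness numeric vesselness map (2D or 3D).
#' @param method list: low and high quantiles of the positive response
#'   distribution (defaults 0.85 / 0.97), minSize (default 5) and
#'   optionally stripes, a \linkS4class{StripeMask} whose bands are
#'   excluded from the threshold estimation (their responses are dominated
#'   by the artifact, not by vessels).
#' @return a \linkS4class{VesselnessMask}.
#' @export
binarizeVesselness <- function(vesselness, method = list()) {
  me <- modifyList(list(low = 0.85, high = 0.97, minSize = 5L,
                        stripes = NULL), method)
  if (any(!is.finite(vesselness))) stop("vesselness map must be finite")
  v <- vesselness
  if (diff(range(v)) < 1e-12) {
    warning("degenerate (all-equal) vesselness map; returning empty mask")
    return(vesselnessMask(array(FALSE, dim(v))))
  }
  vq <- v
  if (!is.null(me$stripes) && length(dim(v)) == 2L &&
      nrow(stripeBands(me$stripes))) {
    b <- stripeBands(me$stripes)
    keep <- rep(TRUE, ncol(v))
    for (i in seq_len(nrow(b))) keep[(b[i, 1] + 1):b[i, 2]] <- FALSE
    vq <- v[, keep]
  }
  vp <- vq[vq > 0]
  thrL <- quantile(vp, me$low, names = FALSE)
  thrH <- quantile(vp, me$high, names = FALSE)
  weak <- v >= thrL
  strong <- v >= thrH
  lab <- ccomponents(weak)
  keepIds <- unique(lab[strong & lab > 0L])
  mask <- array(weak & (lab %in% keepIds), dim(v))
  mask <- removeSmall(mask, me$minSize)
  vesselnessMask(mask)
}
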