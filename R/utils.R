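## Shared numeric helpers.

#' Wrap phase to (-pi, pi]
#' @param phi phase, radians (any magnitude).
#' @return wrapped phase.
#' @export
wrapPhase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Expected Doppler phase for a moving scatterer
#'
#' The phase accumulated between the two A-scans of a Doppler pair:
#' \eqn{\Delta\phi = 4\pi n v \cos\theta_z \Delta t / \lambda_0}, wrapped to
#' (-pi, pi].
#'
#' @param speed scatterer speed, micrometres/second.
#' @param thetaZ Doppler angle, degrees.
#' @param params an \linkS4class{AcquisitionParams}.
#' @param wrap wrap to (-pi, pi] (default TRUE).
#' @return phase difference, radians.
#' @export
dopplerPhase <- function(speed, thetaZ, params, wrap = TRUE) {
  phi <- 4 * pi * params@nTissue * speed * cos(thetaZ * pi / 180) *
    params@dtODT / params@lambda0
  if (wrap) wrapPhase(phi) else phi
}

#' Relative change (b - a) / a
#'
#' The common form behind the ratio image, relative diameter change, capillary
#' density change and relative flow change. Entries with |a| below
#' \code{floor} are returned as NA (masked), never +/-Inf.
#'
#' @param a baseline value(s).
#' @param b follow-up value(s).
#' @param floor magnitude threshold on the baseline.
#' @return (b - a) / a with sub-floor baselines masked as NA.
#' @export
relativeChange <- function(a, b, floor = 0) {
  out <- (b - a) / a
  out[abs(a) < floor | a == 0] <- NA_real_
  out
}

#' Dice overlap of two binary masks
#' @param a,b logical arrays of identical shape.
#' @export
diceOverlap <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

## Gaussian and derivative-of-Gaussian 1D kernels
gaussKernel <- function(sigma, order = 0L, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(order + 1L,
    g,
    -x / sigma^2 * g,
    (x^2 - sigma^2) / sigma^4 * g
  )
  ## truncation leaves derivative kernels with a small non-zero sum, which
  ## turns constant regions into spurious responses; re-centre exactly
  if (order > 0L) k <- k - sum(k) / length(k)
  k
}

## Separable filtering of a 2D/3D array (replicate padding).
sepFilter <- function(vol, kz, kx = kz, ky = kz) {
  d <- dim(vol)
  if (length(d) == 2L) d <- c(d, 1L)
  v <- array(as.numeric(vol), d)
  if (length(kz) > 1L) v <- .convAxis(v, d, kz, 0L)
  if (length(kx) > 1L) v <- .convAxis(v, d, kx, 1L)
  if (d[3L] > 1L && length(ky) > 1L) v <- .convAxis(v, d, ky, 2L)
  if (length(dim(vol)) == 2L) dim(v) <- dim(vol)
  v
}

gaussSmooth <- function(vol, sigma) {
  k <- gaussKernel(sigma)
  sepFilter(vol, k, k, k)
}

## Box (moving-average) filter over (z, x) of a (z, x[, y]) array.
boxFilterZX <- function(vol, win) {
  d <- dim(vol)
  if (length(d) == 2L) d3 <- c(d, 1L) else d3 <- d
  v <- array(as.numeric(vol), d3)
  if (win[1L] > 1L) v <- .convAxis(v, d3, rep(1 / win[1L], win[1L]), 0L)
  if (win[2L] > 1L) v <- .convAxis(v, d3, rep(1 / win[2L], win[2L]), 1L)
  dim(v) <- d
  v
}

#' Derive a reproducible child seed for a named stage
#'
#' A single pipeline seed fans out to per-stage seeds by stable hashing of
#' the stage name, so adding a stage does not perturb its siblings. The
#' result is kept below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage stage name.
#' @return integer child seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% (2^31 - 1))
}

## Connected components and counts (2D/8-conn or 3D/26-conn).
ccomponents <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  lab <- .ccLabel(array(as.logical(mask), d), d)
  n <- attr(lab, "n")
  dim(lab) <- dim(mask)
  attr(lab, "n") <- n
  lab
}

ccCount <- function(mask, minSize = 1L) {
  lab <- ccomponents(mask)
  if (attr(lab, "n") == 0L) return(0L)
  sum(tabulate(lab[lab > 0L]) >= minSize)
}

## Remove connected components smaller than minSize voxels.
removeSmall <- function(mask, minSize) {
  if (minSize <= 1L || !any(mask)) return(mask)
  lab <- ccomponents(mask)
  keep <- which(tabulate(lab[lab > 0L]) >= minSize)
  out <- array(lab %in% keep & mask, dim(mask))
  out
}

## Euclidean distance transform (distance of foreground to background), in
## physical units given per-axis spacing.
distTransform <- function(mask, spacing = rep(1, 3)) {
  d <- dim(mask)
  if (length(d) == 2L) {
    d3 <- c(d, 1L)
    sp <- c(spacing[1:2], 1)
  } else {
    d3 <- d
    sp <- spacing
  }
  dt <- .edt3(array(as.numeric(mask > 0), d3), d3, as.numeric(sp))
  dim(dt) <- dim(mask)
  dt
}

## 2D skeleton (Zhang-Suen thinning).
skeletonize2d <- function(mask) {
  out <- .thin2d(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  out
}

## Length of a 2D skeleton (sum of 8-neighbour link lengths), physical units.
skeletonLength2d <- function(skel, pitch = c(1, 1)) {
  H <- nrow(skel); W <- ncol(skel)
  len <- 0
  ## axial links
  len <- len + sum(skel[-H, ] & skel[-1, ]) * pitch[1]
  len <- len + sum(skel[, -W] & skel[, -1]) * pitch[2]
  ## diagonal links
  dlen <- sqrt(pitch[1]^2 + pitch[2]^2)
  len <- len + sum(skel[-H, -W] & skel[-1, -1]) * dlen
  len <- len + sum(skel[-1, -W] & skel[-H, -1]) * dlen
  len
}

## Canonical JSON + md5 for manifests.
hashObject <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

halfOpenToIdx <- function(range, n) {
  ## 0-based half-open [a, b) -> 1-based R indices; validates bounds
  a <- range[1L]; b <- range[2L]
  if (b <= a) stop("empty half-open range [", a, ", ", b, ")")
  if (a < 0 || b > n) stop("range [", a, ", ", b, ") outside extent ", n)
  seq.int(a + 1L, b)
}
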