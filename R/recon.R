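## Reconstruction of Doppler-flow (phase subtraction) and angiography
## (speckle variance) volumes from repeated-B-scan acquisitions.

#' Reconstruct a Doppler flow volume by phase subtraction
#'
#' The per-voxel phase difference between the two A-scans of a Doppler pair
#' is recovered as the argument of the lag-1 complex autocorrelation along
#' the fast axis: the product of each A-scan with the conjugate of its
#' temporal neighbour, averaged across all repeat frames and (optionally)
#' over a small (z, x) window before the argument is taken. The result lies
#' in (-pi, pi] and is not Doppler-angle corrected.
#'
#' Zero-amplitude voxels have an undefined argument; they are returned as 0
#' and flagged in the \code{lowConfidence} slot.
#'
#' @param acq a \linkS4class{ComplexAcquisition} (>= 2 A-scans per B-scan).
#' @param cfg a \linkS4class{ReconConfig}; \code{phaseWindow} controls the
#'   complex averaging window (c(1, 1) disables it).
#' @return an \linkS4class{ODTVolume} in phase units.
#' @export
phaseSubtractionODT <- function(acq, cfg = reconConfig()) {
  d <- dim(acq@field)
  if (d[2] < 2L) stop("need at least 2 A-scans per Doppler pair")
  nz <- d[1]; nx <- d[2]; nr <- d[3]; ny <- d[4]
  prods <- Conj(acq@field[, -nx, , , drop = FALSE]) *
    acq@field[, -1L, , , drop = FALSE]
  ## average lag-1 products across all repeat frames
  m <- array(prods, c(nz * (nx - 1L), nr, ny))
  P <- array(complex(real = 0), c(nz, nx, ny))
  acc <- m[, 1L, ]
  if (nr > 1L) for (r in 2:nr) acc <- acc + m[, r, ]
  P[, -nx, ] <- array(acc / nr, c(nz, nx - 1L, ny))
  P[, nx, ] <- P[, nx - 1L, ]
  win <- cfg@phaseWindow
  if (any(win > 1L)) {
    re <- boxFilterZX(array(Re(P), dim(P)), win)
    im <- boxFilterZX(array(Im(P), dim(P)), win)
    P <- array(complex(real = re, imaginary = im), dim(P))
  }
  low <- Mod(P) < 1e-12
  dphi <- Arg(P)
  dphi[low] <- 0
  dphi[dphi == -pi] <- pi
  new("ODTVolume", data = dphi, params = acq@params, units = "rad",
      angleCorrected = FALSE, lowConfidence = array(low, dim(dphi)))
}

#' Select the most correlated repeated B-scans
#'
#' Repeated B-scan frames are compared by Pearson correlation of their
#' log-compressed, speckle-averaged (Gaussian-smoothed) intensities, so the
#' statistic reflects bulk frame alignment rather than stochastic speckle
#' or flow decorrelation. The reference is the frame whose (nSelect-1)-th
#' largest correlation to the other frames is highest - it sits in the
#' largest clique of mutually consistent frames, which stays robust even
#' when most frames are corrupted, as long as at least nSelect clean frames
#' exist; frames correlating above \code{rThreshold} with
#' the reference qualify, and if more than \code{nSelect} qualify the
#' \code{nSelect} with the highest mean mutual correlation are kept (ties
#' broken towards lower frame index). If fewer than two frames qualify the
#' best two are returned with a degraded-quality warning flag.
#'
#' @param frames numeric array (z, x, r) of intensity B-scans at one
#'   slow-axis position.
#' @param cfg a \linkS4class{ReconConfig}.
#' @return list: indices (ascending), warn (logical), ref (reference frame).
#' @export
selectCorrelatedBScans <- function(frames, cfg = reconConfig()) {
  d <- dim(frames)
  if (length(d) != 3L || d[3] < 2L) stop("need >= 2 frames (z, x, r)")
  nr <- d[3]
  if (cfg@nSelect > nr) stop("nSelect exceeds the number of frames")
  sk <- gaussKernel(2)
  m <- vapply(seq_len(nr), function(r)
    as.numeric(sepFilter(log1p(frames[, , r]), sk, sk)),
    numeric(d[1] * d[2]))
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    C <- matrix(0, nr, nr)
    for (i in seq_len(nr)) for (j in seq_len(nr))
      C[i, j] <- if (identical(m[, i], m[, j])) 1 else
        if (sds[i] > 0 && sds[j] > 0) cor(m[, i], m[, j]) else 0
  } else C <- cor(m)
  k <- min(cfg@nSelect - 1L, nr - 1L)
  cliq <- vapply(seq_len(nr), function(i)
    sort(C[i, -i], decreasing = TRUE)[k], 1)
  ref <- which.max(cliq)  # ties -> lower index
  qual <- which(C[ref, ] > cfg@rThreshold)
  warn <- FALSE
  if (length(qual) < 2L) {
    warn <- TRUE
    qual <- order(-C[ref, ], seq_len(nr))[1:2]
  } else if (length(qual) > cfg@nSelect) {
    sc <- vapply(qual, function(i) mean(C[i, setdiff(qual, i)]), 1)
    qual <- qual[order(-sc, qual)][seq_len(cfg@nSelect)]
  }
  list(indices = sort(qual), warn = warn, ref = ref)
}

#' Speckle variance of a set of B-scans
#'
#' Per-voxel normalized standard deviation (coefficient of variation) of
#' intensity across frames; voxels with zero mean are defined as 0.
#'
#' @param frames numeric array (z, x, n) of intensity B-scans, n >= 2.
#' @return matrix (z, x) of speckle variance.
#' @export
speckleVarianceOCA <- function(frames) {
  d <- dim(frames)
  if (length(d) != 3L || d[3] < 2L)
    stop("speckle variance needs >= 2 frames")
  m <- matrix(as.numeric(frames), d[1] * d[2], d[3])
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (d[3] - 1L))
  cv <- ifelse(mu == 0, 0, s / mu)
  matrix(cv, d[1], d[2])
}

#' Reconstruct an angiography volume from an acquisition
#'
#' At each slow-axis position the most correlated repeat frames are selected
#' (\code{\link{selectCorrelatedBScans}}) and the speckle variance of their
#' intensities forms the angiography B-scan. Because the coefficient of
#' variation is estimated from few frames it is heavy-tailed in static
#' tissue; a small box average over each B-scan (default 3 voxels along z
#' and x, none along the slow axis, so every slow-axis position keeps
#' identical statistics) reduces that variance before projection without
#' affecting the CoV scale invariance. Set \code{smooth = NULL} for the
#' raw per-voxel CoV.
#'
#' @param acq a \linkS4class{ComplexAcquisition}.
#' @param cfg a \linkS4class{ReconConfig}.
#' @param smooth box-filter width per (z, x, y) axis, or NULL.
#' @return an \linkS4class{OCAVolume}.
#' @export
reconstructOCA <- function(acq, cfg = reconConfig(), smooth = c(3, 3, 1)) {
  d <- dim(acq@field)
  oca <- array(0, d[c(1, 2, 4)])
  used <- vector("list", d[4])
  warn <- logical(d[4])
  for (y in seq_len(d[4])) {
    frames <- Mod(acq@field[, , , y])^2
    sel <- selectCorrelatedBScans(frames, cfg)
    oca[, , y] <- speckleVarianceOCA(frames[, , sel$indices, drop = FALSE])
    used[[y]] <- sel$indices
    warn[y] <- sel$warn
  }
  if (!is.null(smooth) && any(smooth > 1)) {
    oca <- sepFilter(oca, rep(1 / smooth[1], smooth[1]),
                     rep(1 / smooth[2], smooth[2]),
                     rep(1 / smooth[3], smooth[3]))
    oca[oca < 0] <- 0
  }
  new("OCAVolume", data = oca, framesUsed = used, selectionWarn = warn)
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum over a (half-open, 0-based) range of one axis. For
#' Doppler volumes the projection is taken over the phase magnitude; for
#' angiography volumes over the speckle variance.
#'
#' @param volume array, \linkS4class{ODTVolume} or \linkS4class{OCAVolume}.
#' @param axis "z", "x" or "y" (or axis index 1:3).
#' @param range 0-based half-open index interval c(a, b); NULL = full axis.
#' @return 2D matrix over the two remaining axes (in grid order).
#' @export
setGeneric("mipProject", function(volume, axis = "z", range = NULL)
  standardGeneric("mipProject"))

#' @rdname mipProject
setMethod("mipProject", "array", function(volume, axis = "z", range = NULL) {
  ax <- if (is.character(axis)) match(axis, c("z", "x", "y")) else as.integer(axis)
  if (is.na(ax) || ax < 1L || ax > 3L) stop("axis must be z, x or y")
  n <- dim(volume)[ax]
  idx <- if (is.null(range)) seq_len(n) else halfOpenToIdx(range, n)
  sub <- switch(ax,
    volume[idx, , , drop = FALSE],
    volume[, idx, , drop = FALSE],
    volume[, , idx, drop = FALSE])
  apply(sub, setdiff(1:3, ax), max)
})

#' @rdname mipProject
setMethod("mipProject", "ODTVolume", function(volume, axis = "z",
                                              range = NULL) {
  mipProject(abs(volume@data), axis, range)
})

#' @rdname mipProject
setMethod("mipProject", "OCAVolume", function(volume, axis = "z",
                                              range = NULL) {
  mipProject(volume@data, axis, range)
})

#' Relative-change (ratio) image between two Doppler volumes
#'
#' Per voxel (b - a) / a wherever |a| >= floor; voxels with a weaker
#' baseline are masked (NA), never +/-Inf. Both volumes must share grid and
#' units.
#'
#' @param a baseline \linkS4class{ODTVolume} (or array).
#' @param b follow-up volume on the same grid and units.
#' @param floor baseline magnitude threshold.
#' @return numeric array of relative changes with NA outside the valid mask.
#' @export
ratioImage <- function(a, b, floor = 0.05) {
  if (is(a, "ODTVolume") && is(b, "ODTVolume")) {
    if (a@units != b@units) stop("unit mismatch between volumes")
    da <- a@data; db <- b@data
  } else {
    da <- a; db <- b
  }
  if (!all(dim(da) == dim(db))) stop("volumes must share the same grid")
  relativeChange(da, db, floor = floor)
}
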