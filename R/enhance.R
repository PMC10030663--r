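## Self-supervised 3D Doppler-volume enhancement: intensity remapping and
## vessel cropping augmentations, a small U-shaped 3D CNN trained on single
## noisy volumes, and overlap-blended whole-volume inference.

#' Monotone intensity remapping
#'
#' Applies a strictly monotone piecewise-linear map to the vessel-interior
#' voxels of a volume (all voxels when no mask is given). By default the
#' control abscissae are the empirical quantiles of the remapped voxels and
#' the ordinates are drawn uniformly (sorted), producing vessels of
#' different intensities while preserving the rank order of voxels exactly.
#'
#' @param volume numeric array.
#' @param spec an \linkS4class{AugmentationSpec}.
#' @param mask logical array restricting the remap to vessel voxels (NULL =
#'   whole volume).
#' @param controlPoints optional explicit list(x, y) of strictly increasing
#'   control points (overrides the random draw).
#' @param seed seed of the random draw (defaults to the spec seed).
#' @return the remapped volume.
#' @export
intensityRemap <- function(volume, spec = augmentationSpec(), mask = NULL,
                           controlPoints = NULL, seed = spec@seed) {
  sel <- if (is.null(mask)) rep(TRUE, length(volume)) else as.logical(mask)
  vals <- volume[sel]
  if (!length(vals)) return(volume)
  if (is.null(controlPoints)) {
    nc <- spec@nControl
    xs <- quantile(vals, seq(0, 1, length.out = nc + 2L), names = FALSE)
    keep <- !duplicated(xs)
    xs <- xs[keep]
    if (length(xs) < 2L) return(volume)  # constant region: nothing to remap
    ys <- withSeed(seed, {
      lo <- min(vals); hi <- max(vals)
      inner <- sort(runif(length(xs) - 2L, lo, hi))
      c(lo, inner, hi)
    })
    ## enforce strict monotonicity of the ordinates
    eps <- 1e-9 * max(1, diff(range(vals)))
    ys <- cummax(ys + seq_along(ys) * eps)
  } else {
    xs <- controlPoints$x
    ys <- controlPoints$y
    if (any(diff(xs) <= 0) || any(diff(ys) <= 0))
      stop("control points must be strictly monotone")
    if (identical(xs, ys)) return(volume)  # identity map, bit-exact
  }
  f <- approxfun(xs, ys, rule = 2)
  out <- volume
  out[sel] <- f(vals)
  out
}

#' Randomly drop vessel segments from a volume
#'
#' A fraction of approximately \code{spec@cropFraction} of the vessel voxels
#' is removed in contiguous segments (balls of radius drawn from
#' \code{spec@segmentLength} around randomly chosen vessel voxels, clipped
#' exactly to the requested fraction) and replaced by background-level
#' noise. The returned record localizes every dropped voxel exactly, so
#' record and surviving vessel voxels partition the original vessel voxels.
#'
#' @param volume numeric array.
#' @param mask logical vessel mask (non-empty).
#' @param spec an \linkS4class{AugmentationSpec} with cropFraction > 0 for a
#'   non-trivial crop.
#' @param seed seed (defaults to the spec seed).
#' @return list: volume (cropped), record (linear indices of dropped
#'   voxels).
#' @export
vesselCrop <- function(volume, mask, spec = augmentationSpec(),
                       seed = spec@seed) {
  if (!any(mask)) stop("mask is empty")
  f <- spec@cropFraction
  if (f == 0) return(list(volume = volume, record = integer(0)))
  d <- dim(volume)
  vox <- which(mask)
  total <- length(vox)
  target <- round(f * total)
  bg <- volume[!mask]
  bgMed <- median(bg)
  bgMad <- mad(bg)
  withSeed(seed, {
    dropped <- logical(length(volume))
    nDropped <- 0L
    tries <- 0L
    idx3 <- arrayInd(vox, d)
    while (nDropped < target && tries < 1000L) {
      tries <- tries + 1L
      ci <- sample.int(total, 1L)
      ctr <- idx3[ci, ]
      rad <- runif(1, spec@segmentLength[1], spec@segmentLength[2])
      near <- which(abs(idx3[, 1] - ctr[1]) <= rad &
                    abs(idx3[, 2] - ctr[2]) <= rad &
                    abs(idx3[, 3] - ctr[3]) <= rad)
      dd <- sqrt(rowSums((idx3[near, , drop = FALSE] -
                            matrix(ctr, length(near), 3,
                                   byrow = TRUE))^2))
      ball <- vox[near[dd <= rad]]
      new <- ball[!dropped[ball]]
      if (!length(new)) next
      if (nDropped + length(new) > target) {
        ## trim the final segment to land exactly on the requested fraction
        dnew <- dd[dd <= rad][!dropped[ball]]
        new <- new[order(dnew)][seq_len(target - nDropped)]
      }
      dropped[new] <- TRUE
      nDropped <- nDropped + length(new)
    }
    record <- which(dropped)
    if (length(record) >= total)
      stop("cropFraction leaves no vessel segment")
    out <- volume
    out[record] <- bgMed + bgMad * rnorm(length(record))
    list(volume = out, record = record)
  })
}

enhanceNetInit <- function(base = 8L, outScale = 0.05) {
  list(
    c1 = nnInitConv3(3L, 1L, base),
    c2 = nnInitConv3(3L, base, 2L * base),
    c3 = nnInitConv3(3L, 2L * base, 4L * base),
    c4 = nnInitConv3(3L, 4L * base, 4L * base),
    c5 = nnInitConv3(3L, 4L * base, 2L * base),
    c6 = nnInitConv3(3L, 2L * base, base),
    ## residual head: near-identity at init, but with enough signal that
    ## gradients reach the encoder from the first iteration
    out = nnInitConv3(3L, base, 1L, scale = outScale)
  )
}

## U-shaped 3D net; the last decoder conv runs at half resolution before
## the final upsample, which keeps the full-resolution work to the first
## and last (8-channel) layers.
enhanceNetForward <- function(p, x) {
  x4 <- array(x, c(dim(x), 1L))
  a1 <- nnConv3F(x4, p$c1, 1L); h1 <- nnElu(a1$y)
  a2 <- nnConv3F(h1, p$c2, 2L); h2 <- nnElu(a2$y)
  a3 <- nnConv3F(h2, p$c3, 2L); h3 <- nnElu(a3$y)
  a4 <- nnConv3F(h3, p$c4, 1L); h4 <- nnElu(a4$y)
  u1 <- nnUp3F(h4)
  a5 <- nnConv3F(u1, p$c5, 1L); h5 <- nnElu(a5$y) + h2
  a6 <- nnConv3F(h5, p$c6, 1L)
  u2 <- nnUp3F(nnElu(a6$y))
  h6 <- u2 + h1
  o <- nnConv3F(h6, p$out, 1L)
  y <- x + array(o$y, dim(x))
  list(y = y,
       cache = list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
                    o = o, h1 = h1, h2 = h2, h3 = h3, h4 = h4))
}

enhanceNetBackward <- function(p, cache, dyv) {
  dy4 <- array(dyv, c(dim(dyv), 1L))
  bo <- nnConv3B(p$out, cache$o$cache, dy4)
  dh6 <- bo$dx
  dh1skip <- dh6
  dh6p <- nnUp3B(dh6)
  d6 <- nnConv3B(p$c6, cache$a6$cache, dh6p * nnEluGrad(cache$a6$y,
                                                        nnElu(cache$a6$y)))
  dh5 <- d6$dx
  d5 <- nnConv3B(p$c5, cache$a5$cache, dh5 * nnEluGrad(cache$a5$y,
                                                       nnElu(cache$a5$y)))
  dh4 <- nnUp3B(d5$dx)
  dh2skip <- dh5
  d4 <- nnConv3B(p$c4, cache$a4$cache, dh4 * nnEluGrad(cache$a4$y, cache$h4))
  d3 <- nnConv3B(p$c3, cache$a3$cache, d4$dx * nnEluGrad(cache$a3$y,
                                                         cache$h3))
  dh2 <- d3$dx + dh2skip
  d2 <- nnConv3B(p$c2, cache$a2$cache, dh2 * nnEluGrad(cache$a2$y, cache$h2))
  dh1 <- d2$dx + dh1skip
  d1 <- nnConv3B(p$c1, cache$a1$cache, dh1 * nnEluGrad(cache$a1$y, cache$h1))
  list(
    c1 = list(W = d1$gW, b = d1$gb), c2 = list(W = d2$gW, b = d2$gb),
    c3 = list(W = d3$gW, b = d3$gb), c4 = list(W = d4$gW, b = d4$gb),
    c5 = list(W = d5$gW, b = d5$gb), c6 = list(W = d6$gW, b = d6$gb),
    out = list(W = bo$gW, b = bo$gb)
  )
}

## Composite loss: separately averaged L1 over the dropped segments, 0.5 x
## L1 elsewhere and (added by the caller) 0.1 x consistency.
enhanceCompositeL1 <- function(y, target, dropped) {
  nd <- sum(dropped)
  ne <- length(y) - nd
  r <- y - target
  s <- sign(r)
  a <- abs(r)
  lossD <- if (nd > 0) sum(a[dropped]) / nd else 0
  lossE <- sum(a[!dropped]) / ne
  dy <- array(0, dim(y))
  if (nd > 0) dy[dropped] <- s[dropped] / nd
  dy[!dropped] <- 0.5 * s[!dropped] / ne
  list(loss = lossD + 0.5 * lossE, dy = dy)
}

normalizeVolume <- function(v, p1, p99) (v - p1) / (p99 - p1)

## One training observation: patch -> two remapped, cropped, noise-perturbed
## branches with targets and weight maps.
makeEnhanceBranch <- function(patchN, mask, spec, seed) {
  rm <- intensityRemap(patchN, spec, mask = mask, seed = seed)
  cr <- vesselCrop(rm, mask, spec, seed = seed + 1L)
  inp <- cr$volume
  if (spec@noiseSD > 0) {
    inp <- withSeed(seed + 2L, inp + rnorm(length(inp), sd = spec@noiseSD))
    dim(inp) <- dim(patchN)
  }
  dropped <- array(FALSE, dim(patchN))
  dropped[cr$record] <- TRUE
  list(input = inp, target = rm, dropped = dropped)
}

#' Train the self-supervised 3D enhancement model
#'
#' A U-shaped 3D CNN (3 levels, gated by nothing but plain ELU convolutions,
#' residual output initialized to the identity) is trained on single noisy
#' volumes only: each iteration draws a patch, builds two independently
#' intensity-remapped branches, drops vessel segments from each, perturbs
#' the inputs with additive noise and minimizes the composite loss
#' L1 on the dropped segments + 0.5 x L1 elsewhere + 0.1 x L1 consistency
#' between the two branch predictions. No clean targets exist anywhere in
#' the interface.
#'
#' @param volumes list of noisy 3D arrays (or \linkS4class{ODTVolume}s; the
#'   phase magnitude is used).
#' @param spec an \linkS4class{AugmentationSpec}.
#' @param config list: iterations (default 200), patch (default 32), lr,
#'   baseChannels, seed, oofRadii (provisional-mask scales).
#' @return a trained \linkS4class{ConvModel} of kind "enhance3d" whose
#'   manifest records the normalization percentiles and per-iteration
#'   losses.
#' @export
trainEnhancer <- function(volumes, spec = augmentationSpec(),
                          config = list()) {
  cf <- modifyList(list(iterations = 200L, patch = 32L, lr = 5e-3,
                        batchSize = 2L, baseChannels = 8L, seed = 1L,
                        oofRadii = c(1.5, 2.5),
                        maskMethod = list(low = 0.95, high = 0.99,
                                          minSize = 10L)),
                   config)
  if (!length(volumes)) stop("need at least one volume")
  vols <- lapply(volumes, function(v)
    if (is(v, "ODTVolume")) abs(v@data) else abs(v))
  allv <- unlist(lapply(vols, as.numeric))
  p1 <- quantile(allv, 0.01, names = FALSE)
  p99 <- quantile(allv, 0.99, names = FALSE)
  volsN <- lapply(vols, normalizeVolume, p1 = p1, p99 = p99)
  ## provisional vessel masks from oriented flux on the noisy volumes;
  ## conservative thresholds: only confident vessel voxels are cropped, so
  ## the restoration task is not polluted by background noise specks
  masks <- lapply(volsN, function(v)
    maskArray(binarizeVesselness(oofVesselness(v, cf$oofRadii)$response,
                                 cf$maskMethod)))
  withSeed(cf$seed, {
    p <- enhanceNetInit(base = cf$baseChannels)
    st <- nnAdamInit(p)
    losses <- numeric(cf$iterations)
    ps <- cf$patch
    drawPatch <- function() {
      vi <- sample.int(length(volsN), 1L)
      d <- dim(volsN[[vi]])
      if (any(d < ps)) stop("volume smaller than the training patch")
      for (att in 1:20) {
        o <- vapply(d, function(n) sample.int(n - ps + 1L, 1L), 1L)
        idx <- lapply(1:3, function(k) o[k]:(o[k] + ps - 1L))
        mk <- masks[[vi]][idx[[1]], idx[[2]], idx[[3]]]
        if (mean(mk) > 0.01 || att == 20L)
          return(list(patch = volsN[[vi]][idx[[1]], idx[[2]], idx[[3]]],
                      mask = mk))
      }
    }
    ## fixed evaluation set: the manifest's init/final losses are computed
    ## on the same deterministic augmented observations before and after
    ## training, so the ratio is not confounded by patch-to-patch variance
    evalSet <- lapply(1:8, function(i) {
      dp <- drawPatch()
      if (!any(dp$mask)) return(NULL)
      list(b1 = makeEnhanceBranch(dp$patch, dp$mask, spec, 7000L + i),
           b2 = makeEnhanceBranch(dp$patch, dp$mask, spec, 8000L + i))
    })
    evalSet <- Filter(Negate(is.null), evalSet)
    evalLoss <- function(p) {
      mean(vapply(evalSet, function(e) {
        y1 <- enhanceNetForward(p, e$b1$input)$y
        y2 <- enhanceNetForward(p, e$b2$input)$y
        (enhanceCompositeL1(y1, e$b1$target, e$b1$dropped)$loss +
           enhanceCompositeL1(y2, e$b2$target, e$b2$dropped)$loss) / 2 +
          0.1 * mean(abs(y1 - y2))
      }, 1))
    }
    initLoss <- evalLoss(p)
    for (t in seq_len(cf$iterations)) {
      gr <- NULL
      lossAcc <- 0
      nb <- 0L
      for (bi in seq_len(cf$batchSize)) {
        dp <- drawPatch()
        if (!any(dp$mask)) next
        s0 <- sample.int(2^30, 1L)
        b1 <- makeEnhanceBranch(dp$patch, dp$mask, spec, s0)
        b2 <- makeEnhanceBranch(dp$patch, dp$mask, spec, s0 + 101L)
        f1 <- enhanceNetForward(p, b1$input)
        f2 <- enhanceNetForward(p, b2$input)
        l1 <- enhanceCompositeL1(f1$y, b1$target, b1$dropped)
        l2 <- enhanceCompositeL1(f2$y, b2$target, b2$dropped)
        cons <- mean(abs(f1$y - f2$y))
        loss <- (l1$loss + l2$loss) / 2 + 0.1 * cons
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at iteration ", t)
        lossAcc <- lossAcc + loss
        nb <- nb + 1L
        dcons <- sign(f1$y - f2$y) / length(f1$y)
        dy1 <- l1$dy / 2 + 0.1 * dcons
        dy2 <- l2$dy / 2 - 0.1 * dcons
        gr1 <- enhanceNetBackward(p, f1$cache, dy1)
        gr2 <- enhanceNetBackward(p, f2$cache, dy2)
        for (nm in names(gr1))
          for (pt in names(gr1[[nm]])) {
            g <- gr1[[nm]][[pt]] + gr2[[nm]][[pt]]
            if (is.null(gr)) gr1[[nm]][[pt]] <- g
            else gr[[nm]][[pt]] <- gr[[nm]][[pt]] + g
          }
        if (is.null(gr)) gr <- gr1
      }
      if (nb == 0L) next
      losses[t] <- lossAcc / nb
      for (nm in names(gr))
        for (pt in names(gr[[nm]]))
          gr[[nm]][[pt]] <- gr[[nm]][[pt]] / nb
      ## cosine learning-rate decay
      lrT <- cf$lr * 0.5 * (1 + cos(pi * (t - 1) / cf$iterations))
      upd <- nnAdamStep(p, gr, st, lr = lrT)
      p <- upd$params
      st <- upd$state
    }
    new("ConvModel", kind = "enhance3d", params = p, config = cf,
        manifest = list(seed = cf$seed, iterations = cf$iterations,
                        losses = losses, initLoss = initLoss,
                        finalLoss = evalLoss(p),
                        normalization = list(p1 = p1, p99 = p99)),
        trained = TRUE)
  })
}

#' Enhance a Doppler volume with a trained model
#'
#' The volume is normalized with the percentiles recorded in the training
#' manifest; enhancement operates on the phase magnitude and the flow sign
#' is reattached afterwards, so flow direction is never flipped. Volumes
#' larger than the training patch are processed in overlapping tiles with
#' triangular-window blending.
#'
#' @param volume an \linkS4class{ODTVolume} or numeric array (every
#'   dimension must be at least the training patch size).
#' @param model a trained "enhance3d" \linkS4class{ConvModel}.
#' @return enhanced volume (same class as the input).
#' @export
enhanceVolume <- function(volume, model) {
  if (!is(model, "ConvModel") || !model@trained || model@kind != "enhance3d")
    stop("model must be a trained enhance3d ConvModel")
  isODT <- is(volume, "ODTVolume")
  v <- if (isODT) volume@data else volume
  d <- dim(v)
  ps <- model@config$patch
  if (any(d < ps))
    stop("volume smaller than the model's receptive field (", ps, "^3)")
  nz <- model@manifest$normalization
  a <- normalizeVolume(abs(v), nz[["p1"]], nz[["p99"]])
  taper <- pmin(seq_len(ps), rev(seq_len(ps)))
  w1 <- taper / max(taper)
  wp <- array(outer(outer(w1, w1), w1), c(ps, ps, ps))
  acc <- array(0, d)
  wac <- array(0, d)
  starts <- lapply(d, function(n)
    unique(c(seq(1L, n - ps + 1L, by = ps %/% 2L), n - ps + 1L)))
  for (i in starts[[1]]) for (j in starts[[2]]) for (k in starts[[3]]) {
    iz <- i:(i + ps - 1L); ix <- j:(j + ps - 1L); iy <- k:(k + ps - 1L)
    fw <- enhanceNetForward(model@params, a[iz, ix, iy])
    acc[iz, ix, iy] <- acc[iz, ix, iy] + fw$y * wp
    wac[iz, ix, iy] <- wac[iz, ix, iy] + wp
  }
  yN <- acc / wac
  yAbs <- pmax(0, yN * (nz[["p99"]] - nz[["p1"]]) + nz[["p1"]])
  out <- sign(v) * yAbs
  if (isODT) {
    res <- volume
    if (volume@units == "rad") out <- pmin(pmax(out, -pi), pi)
    res@data <- out
    res
  } else out
}
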