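## Self-supervised structure-aware inpainting of binarized vesselness masks
## across stripe (bulk-motion) bands, and the mask-multiplication
## enhancement of the en-face angiography image.

## Normalized gradient-magnitude guidance channel from the raw MIP.
gradGuidance <- function(mip) {
  d3 <- c(dim(mip), 1L)
  g <- gaussSmooth(array(as.numeric(mip), d3), 1)
  dk <- c(-0.5, 0, 0.5)
  gm <- sqrt(.convAxis(g, d3, dk, 0L)^2 + .convAxis(g, d3, dk, 1L)^2)
  hi <- quantile(gm, 0.99, names = FALSE)
  out <- if (hi > 0) pmin(gm / hi, 1) else gm
  matrix(out, dim(mip)[1], dim(mip)[2])
}

drawStripeWidth <- function(widthRange) {
  round(exp(runif(1, log(widthRange[1]), log(widthRange[2]))))
}

## Corrupt a MIP patch inside a stripe band the way bulk motion does:
## structure is suppressed and replaced by a bright decorrelation floor.
simulateStripeOnMip <- function(mip, cols, strength = 0.8) {
  lvl <- quantile(mip, 0.9, names = FALSE)
  n <- length(mip[, cols])
  mip[, cols] <- (1 - strength) * mip[, cols] +
    strength * (lvl * (0.7 + 0.6 * runif(n)))
  mip
}

#' Build self-supervised inpainting training pairs
#'
#' Synthetic stripe bands (widths log-uniform over \code{widthRange}) are
#' drawn over clean regions of the binarized vesselness mask only, so the
#' original mask is a free supervision target: each pair holds the occluded
#' mask patch, a stripe-indicator channel, a gradient-guidance channel
#' computed from the (stripe-corrupted) MIP, the original mask patch as
#' target and a loss weight map concentrated on the occluded band.
#'
#' @param mask a \linkS4class{VesselnessMask} (en-face, x by y).
#' @param mip the raw angiography MIP the mask came from.
#' @param stripes a \linkS4class{StripeMask} of real (to-be-avoided) bands;
#'   NULL when the image is clean.
#' @param n number of patches.
#' @param patch patch side, pixels.
#' @param widthRange synthetic stripe width range, pixels (0 allowed: the
#'   input then equals the target).
#' @param outsideWeight loss weight outside the occluded band.
#' @param seed integer seed; the patch inventory is deterministic under it.
#' @return list of pairs: input (patch x patch x 3), target, weight,
#'   occluded (logical columns).
#' @export
makeInpaintTrainingPairs <- function(mask, mip, stripes = NULL, n = 200L,
                                     patch = 64L, widthRange = c(4, 32),
                                     outsideWeight = 0.1, seed = 1L) {
  m <- maskArray(mask)
  d <- dim(m)
  if (any(d < patch)) stop("image smaller than the requested patch")
  bad <- logical(d[2])
  if (!is.null(stripes) && nrow(stripeBands(stripes))) {
    b <- stripeBands(stripes)
    for (i in seq_len(nrow(b))) bad[(b[i, 1] + 1):b[i, 2]] <- TRUE
  }
  ## patches may overlap real stripe bands, but supervision comes from the
  ## clear area only: real-band columns are zeroed and flagged exactly as at
  ## inference and carry zero loss weight. Synthetic stripes are drawn over
  ## clean columns only. A patch needs at least one clean run wider than the
  ## largest requested stripe.
  maxW <- max(widthRange)
  cleanRun <- function(cols) {
    r <- rle(!bad[cols])
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }
  okStart <- which(vapply(seq_len(d[2] - patch + 1L), function(j)
    cleanRun(j:(j + patch - 1L)) > maxW, TRUE))
  if (!length(okStart)) stop("no clean area wide enough for a patch")
  withSeed(seed, {
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      x0 <- sample.int(d[1] - patch + 1L, 1L)
      y0 <- okStart[sample.int(length(okStart), 1L)]
      cols <- y0:(y0 + patch - 1L)
      real <- bad[cols]
      tg <- m[x0:(x0 + patch - 1L), cols] * 1
      sub <- mip[x0:(x0 + patch - 1L), cols]
      w <- if (maxW > 0) drawStripeWidth(widthRange) else 0L
      occ <- rep(FALSE, patch)
      if (w > 0) {
        ## candidate synthetic band: w consecutive clean columns
        free <- which(vapply(seq_len(patch - w + 1L), function(c0)
          !any(real[c0:(c0 + w - 1L)]), TRUE))
        c0 <- free[sample.int(length(free), 1L)]
        occ[c0:(c0 + w - 1L)] <- TRUE
        sub <- simulateStripeOnMip(sub, which(occ))
      }
      inp <- tg
      inp[, occ | real] <- 0
      ind <- matrix(rep(as.numeric(occ | real), each = patch), patch, patch)
      guide <- gradGuidance(sub)
      input <- array(c(inp, ind, guide), c(patch, patch, 3L))
      weight <- matrix(outsideWeight, patch, patch)
      weight[, occ] <- 1
      weight[, real] <- 0
      pairs[[i]] <- list(input = input, target = tg, weight = weight,
                         occluded = occ)
    }
    pairs
  })
}

inpaintNetInit <- function(cin = 3L, base = 8L) {
  list(
    g1f = nnInitConv2(3L, cin, base),        g1g = nnInitConv2(3L, cin, base),
    g2f = nnInitConv2(3L, base, 2L * base),  g2g = nnInitConv2(3L, base, 2L * base),
    g3f = nnInitConv2(3L, 2L * base, 4L * base),
    g3g = nnInitConv2(3L, 2L * base, 4L * base),
    g4f = nnInitConv2(3L, 4L * base, 4L * base),
    g4g = nnInitConv2(3L, 4L * base, 4L * base),
    g5f = nnInitConv2(3L, 4L * base, 2L * base),
    g5g = nnInitConv2(3L, 4L * base, 2L * base),
    g6f = nnInitConv2(3L, 2L * base, base),  g6g = nnInitConv2(3L, 2L * base, base),
    out = nnInitConv2(3L, base, 1L, scale = 0.1)
  )
}

inpaintNetForward <- function(p, x) {
  a1 <- nnGated2F(x, p$g1f, p$g1g, 1L)
  a2 <- nnGated2F(a1$h, p$g2f, p$g2g, 2L)
  a3 <- nnGated2F(a2$h, p$g3f, p$g3g, 2L)
  a4 <- nnGated2F(a3$h, p$g4f, p$g4g, 1L)
  u1 <- nnUp2F(a4$h)
  a5 <- nnGated2F(u1, p$g5f, p$g5g, 1L)
  h5 <- a5$h + a2$h
  u2 <- nnUp2F(h5)
  a6 <- nnGated2F(u2, p$g6f, p$g6g, 1L)
  h6 <- a6$h + a1$h
  o <- nnConv2F(h6, p$out, 1L)
  list(z = o$y[, , 1],
       cache = list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
                    o = o))
}

inpaintNetBackward <- function(p, cache, dz) {
  dz3 <- array(dz, c(dim(dz), 1L))
  bo <- nnConv2B(p$out, cache$o$cache, dz3)
  d6 <- nnGated2B(p$g6f, p$g6g, cache$a6$cache, bo$dx)
  dh5 <- nnUp2B(d6$dx)
  d5 <- nnGated2B(p$g5f, p$g5g, cache$a5$cache, dh5)
  da4 <- nnUp2B(d5$dx)
  d4 <- nnGated2B(p$g4f, p$g4g, cache$a4$cache, da4)
  d3 <- nnGated2B(p$g3f, p$g3g, cache$a3$cache, d4$dx)
  da2 <- d3$dx + dh5          # skip connection into level 2
  d2 <- nnGated2B(p$g2f, p$g2g, cache$a2$cache, da2)
  da1 <- d2$dx + bo$dx        # skip connection into level 1
  d1 <- nnGated2B(p$g1f, p$g1g, cache$a1$cache, da1)
  list(
    g1f = list(W = d1$f$gW, b = d1$f$gb), g1g = list(W = d1$g$gW, b = d1$g$gb),
    g2f = list(W = d2$f$gW, b = d2$f$gb), g2g = list(W = d2$g$gW, b = d2$g$gb),
    g3f = list(W = d3$f$gW, b = d3$f$gb), g3g = list(W = d3$g$gW, b = d3$g$gb),
    g4f = list(W = d4$f$gW, b = d4$f$gb), g4g = list(W = d4$g$gW, b = d4$g$gb),
    g5f = list(W = d5$f$gW, b = d5$f$gb), g5g = list(W = d5$g$gW, b = d5$g$gb),
    g6f = list(W = d6$f$gW, b = d6$f$gb), g6g = list(W = d6$g$gW, b = d6$g$gb),
    out = list(W = bo$gW, b = bo$gb)
  )
}

inpaintEvalLoss <- function(p, pairs) {
  mean(vapply(pairs, function(pr) {
    fw <- inpaintNetForward(p, pr$input)
    nnBceLoss(fw$z, pr$target, pr$weight)$loss
  }, 1))
}

#' Train the structure-aware inpainting model
#'
#' A 3-level encoder-decoder with gated convolutions at each level and skip
#' connections, trained with weighted binary cross-entropy (full weight
#' inside the occluded band, \code{outsideWeight} elsewhere) by Adam, one
#' patch per iteration. All randomness passes through one seeded generator,
#' so the training manifest is identical across runs on one platform.
#'
#' @param pairs training pairs from \code{\link{makeInpaintTrainingPairs}}.
#' @param config list: iterations (default 300), lr, baseChannels, seed.
#' @return a trained \linkS4class{ConvModel} of kind "inpaint2d".
#' @export
trainInpainting <- function(pairs, config = list()) {
  cf <- modifyList(list(iterations = 300L, lr = 2e-3, baseChannels = 8L,
                        seed = 1L), config)
  if (!length(pairs)) stop("need at least one training pair")
  withSeed(cf$seed, {
    p <- inpaintNetInit(cin = 3L, base = cf$baseChannels)
    evalSet <- pairs[seq_len(min(8L, length(pairs)))]
    initLoss <- inpaintEvalLoss(p, evalSet)
    st <- nnAdamInit(p)
    losses <- numeric(cf$iterations)
    for (t in seq_len(cf$iterations)) {
      pr <- pairs[[sample.int(length(pairs), 1L)]]
      fw <- inpaintNetForward(p, pr$input)
      ls <- nnBceLoss(fw$z, pr$target, pr$weight)
      if (!is.finite(ls$loss))
        stop("training diverged (non-finite loss) at iteration ", t)
      losses[t] <- ls$loss
      gr <- inpaintNetBackward(p, fw$cache, ls$dz)
      upd <- nnAdamStep(p, gr, st, lr = cf$lr)
      p <- upd$params
      st <- upd$state
    }
    finalLoss <- inpaintEvalLoss(p, evalSet)
    new("ConvModel", kind = "inpaint2d", params = p, config = cf,
        manifest = list(seed = cf$seed, iterations = cf$iterations,
                        losses = losses, initLoss = initLoss,
                        finalLoss = finalLoss),
        trained = TRUE)
  })
}

#' Inpaint stripe bands of a vesselness mask
#'
#' Pixels outside the stripe bands are returned bit-exact; inside each band
#' the binary values are predicted by the trained gated-convolution model
#' from the surrounding mask context and the gradient-guidance channel of
#' the raw MIP, and the provenance of those pixels is set to inpainted.
#'
#' @param mask a \linkS4class{VesselnessMask} (en-face).
#' @param stripes a \linkS4class{StripeMask}; empty mask returns the input
#'   unchanged.
#' @param model a trained "inpaint2d" \linkS4class{ConvModel}.
#' @param mip raw angiography MIP for the guidance channel.
#' @param patch inference tile side.
#' @return the inpainted \linkS4class{VesselnessMask}.
#' @export
inpaintStripes <- function(mask, stripes, model, mip, patch = 64L) {
  if (!is(model, "ConvModel") || !model@trained || model@kind != "inpaint2d")
    stop("model must be a trained inpaint2d ConvModel")
  b <- stripeBands(stripes)
  m0 <- maskArray(mask)
  if (!nrow(b)) return(mask)
  d <- dim(m0)
  if (any(b[, 2] > d[2])) stop("stripes outside mask bounds")
  stripeCols <- logical(d[2])
  for (i in seq_len(nrow(b))) stripeCols[(b[i, 1] + 1):b[i, 2]] <- TRUE
  work <- m0 * 1
  work[, stripeCols] <- 0
  guide <- gradGuidance(mip)
  prob <- matrix(0, d[1], d[2])
  wsum <- matrix(0, d[1], d[2])
  taper <- pmin(seq_len(patch), rev(seq_len(patch)))
  wpatch <- outer(taper, taper, pmin) / (patch / 2)
  xs <- unique(c(seq(1L, max(1L, d[1] - patch + 1L), by = patch %/% 2L),
                 max(1L, d[1] - patch + 1L)))
  for (i in seq_len(nrow(b))) {
    mid <- (b[i, 1] + b[i, 2]) / 2
    ys <- round(seq(mid - patch / 2, by = patch %/% 2,
                    length.out = max(1L, ceiling((b[i, 2] - b[i, 1]) /
                                                   (patch %/% 2)))))
    ys <- unique(pmin(pmax(ys + 1L, 1L), d[2] - patch + 1L))
    for (y0 in ys) for (x0 in xs) {
      cols <- y0:(y0 + patch - 1L)
      rows <- x0:(x0 + patch - 1L)
      ind <- matrix(rep(as.numeric(stripeCols[cols]), each = patch),
                    patch, patch)
      input <- array(c(work[rows, cols], ind, guide[rows, cols]),
                     c(patch, patch, 3L))
      fw <- inpaintNetForward(model@params, input)
      prob[rows, cols] <- prob[rows, cols] + nnSigmoid(fw$z) * wpatch
      wsum[rows, cols] <- wsum[rows, cols] + wpatch
    }
  }
  filled <- m0
  sel <- outer(rep(TRUE, d[1]), stripeCols) & wsum > 0
  filled[sel] <- (prob[sel] / wsum[sel]) > 0.5
  inp <- inpaintedArray(mask)
  inp[sel] <- TRUE
  vesselnessMask(filled, inp)
}

#' Mask-multiplication enhancement of an angiography MIP
#'
#' Elementwise product of the MIP with the (inpainted) binarized vesselness
#' mask: background is exactly 0, foreground keeps its input value, and the
#' operation is idempotent.
#'
#' @param mip en-face angiography MIP.
#' @param mask a \linkS4class{VesselnessMask} of the same shape.
#' @return the enhanced MIP matrix.
#' @export
enhanceOCA <- function(mip, mask) {
  m <- maskArray(mask)
  if (!all(dim(mip) == dim(m))) stop("MIP and mask shapes differ")
  mip * m
}
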