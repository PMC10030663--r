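## Shared fixtures, built lazily and cached for the whole test session.
## Everything is generated in code under fixed seeds; no data files.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

## Noise-free acquisition of a branching tree: the forward phase model is
## exact, so Doppler round trips can be checked to float tolerance.
fxNoiseFree <- function() fx("noiseFree", function() {
  params <- acquisitionParams(nRepeats = 6L)
  tree <- generateVesselTree(11, depth = 2,
                             domain = c(0, 192, 0, 192, 0, 192))
  acq <- simulateAcquisition(tree, params,
                             noise = list(speckle = FALSE, additive = 0),
                             seed = 11)
  list(params = params, tree = tree, acq = acq,
       odt = phaseSubtractionODT(acq, reconConfig(phaseWindow = c(1L, 1L))))
})

## Speckle acquisition with default noise (the realistic regime).
fxSpeckle <- function() fx("speckle", function() {
  params <- acquisitionParams()
  tree <- generateVesselTree(5, depth = 2,
                             domain = c(0, 192, 0, 192, 0, 192))
  acq <- simulateAcquisition(tree, params, noise = list(), seed = 2)
  list(params = params, tree = tree, acq = acq)
})

## Voxels whose fast-axis neighbourhood carries a homogeneous forward phase
## (away from lumen boundaries), where the lag-1 model is exact.
homogeneousPhaseVoxels <- function(truth, window = 1L) {
  d <- dim(truth$dphi)
  ok <- array(TRUE, d)
  for (s in seq_len(window)) {
    same <- array(FALSE, d)
    same[, 1:(d[2] - s), ] <-
      truth$dphi[, 1:(d[2] - s), ] == truth$dphi[, (1 + s):d[2], ]
    ok <- ok & same
  }
  ok & truth$label > 0 & !truth$aliased & abs(truth$dphi) > 1e-6
}

## Synthetic 3D cylinder at a given angle from the beam axis (z-x plane).
cylinderVolume <- function(thetaDeg, n = 48L, radius = 4) {
  th <- thetaDeg * pi / 180
  u <- c(cos(th), sin(th), 0)
  c0 <- rep((n + 1) / 2, 3)
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  p <- sweep(idx, 2, c0)
  t <- p %*% u
  d2 <- rowSums((p - t %*% t(u))^2)
  v <- array(0, c(n, n, n))
  v[d2 <= radius^2] <- 1
  v
}

## Straight-tube 2D mask (x along rows), used by inpainting tests.
tubeMask2d <- function(nx, ny, row, halfwidth) {
  m <- matrix(FALSE, nx, ny)
  m[(row - halfwidth):(row + halfwidth), ] <- TRUE
  m
}

## Stripe-path fixture: tree phantom over a long slow axis with three
## full-scramble motion bands, reconstructed angiography, detected stripes,
## masks and a trained inpainting model (desk scale: 300 iterations).
fxStripePath <- function() fx("stripePath", function() {
  params <- acquisitionParams()
  tree <- generateVesselTree(5, depth = 2,
                             domain = c(0, 192, 0, 192, 0, 384))
  acq <- simulateAcquisition(tree, params, noise = list(), seed = 2)
  d <- dim(acqField(acq))
  bands <- list(20:25, 70:76, 100:103)
  sc <- matrix(FALSE, d[3], d[4])
  withSeed(4, for (b in bands) for (y in b)
    sc[sample.int(d[3], d[3] - 1L), y] <- TRUE)
  acqS <- injectBulkMotion(acq, motionTrace(matrix(0, d[3], d[4]), sc),
                           seed = 5)
  oca <- reconstructOCA(acqS)
  mip <- mipProject(oca)
  stripes <- detectStripes(mip)
  oof <- oofVesselness(mip, radii = c(1.5, 2.5, 4))
  maskRaw <- binarizeVesselness(oof$response)
  mask <- binarizeVesselness(oof$response, list(stripes = stripes))
  pairs <- makeInpaintTrainingPairs(mask, mip, stripes, n = 120L, seed = 1)
  model <- trainInpainting(pairs, list(iterations = 300L, seed = 1))
  filled <- inpaintStripes(mask, stripes, model, mip)
  truthMask <- apply(acqTruth(acq)$label > 0, c(2, 3), any)
  list(params = params, tree = tree, acq = acq, bands = bands, sc = sc,
       acqS = acqS, oca = oca, mip = mip, stripes = stripes,
       maskRaw = maskRaw, mask = mask, pairs = pairs, model = model,
       filled = filled, truthMask = truthMask)
})

## Straight-vessel stripe fixture for the connectivity check.
fxStraightVessel <- function() fx("straightVessel", function() {
  params <- acquisitionParams()
  seg <- data.frame(id = 1L, parent = NA_integer_, z0 = 60, x0 = 96,
                    y0 = 8, z1 = 60, x1 = 96, y1 = 376, radius = 7,
                    speed = 60, class = "arteriole")
  tree <- vesselTree(seg, flowSense = 1, domain = c(0, 192, 0, 192, 0, 384))
  acq <- simulateAcquisition(tree, params, noise = list(), seed = 3)
  d <- dim(acqField(acq))
  stripe <- 61:72  # 12 slow-axis positions
  sc <- matrix(FALSE, d[3], d[4])
  withSeed(2, for (y in stripe) sc[sample.int(d[3], d[3] - 1L), y] <- TRUE)
  acqS <- injectBulkMotion(acq, motionTrace(matrix(0, d[3], d[4]), sc),
                           seed = 5)
  mip <- mipProject(reconstructOCA(acqS))
  stripes <- stripeMask(bands = cbind(60L, 72L), scores = 10,
                        nSlow = d[4])
  truthMask <- apply(acqTruth(acq)$label > 0, c(2, 3), any)
  mask <- vesselnessMask(truthMask)
  pairs <- makeInpaintTrainingPairs(mask, mip, stripes, n = 120L, seed = 1)
  model <- trainInpainting(pairs, list(iterations = 300L, seed = 1))
  filled <- inpaintStripes(mask, stripes, model, mip)
  list(stripe = stripe, mip = mip, stripes = stripes, mask = mask,
       truthMask = truthMask, model = model, filled = filled)
})

## Noisy Doppler volume + trained 3D enhancement model (desk scale:
## 200 iterations, 32^3 patches).
fxEnhance <- function() fx("enhance", function() {
  params <- acquisitionParams(nRepeats = 6L)
  tree <- generateVesselTree(5, depth = 2,
                             domain = c(0, 192, 0, 192, 0, 192))
  acq <- simulateAcquisition(tree, params,
                             noise = list(speckle = FALSE, additive = 0,
                                          phaseNoise = 0.25),
                             seed = 2)
  odt <- phaseSubtractionODT(acq, reconConfig(phaseWindow = c(1L, 1L)))
  spec <- augmentationSpec(seed = 1L)
  model <- trainEnhancer(list(odt), spec,
                         list(iterations = 200L, patch = 32L, seed = 1L))
  list(params = params, tree = tree, acq = acq, odt = odt, spec = spec,
       model = model, enh = enhanceVolume(odt, model),
       vesselMask = acqTruth(acq)$label > 0L)
})

cnrOf <- function(a, vm) (mean(a[vm]) - mean(a[!vm])) / sd(a[!vm])

skeletonComponents <- function(mask2d) ccCount(skeletonize2d(mask2d))
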