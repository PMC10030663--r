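test_that("vessel trees honour depth, branching and the diving range", {
  t0 <- generateVesselTree(1, depth = 0)
  expect_identical(nrow(treeSegments(t0)), 1L)

  t3 <- generateVesselTree(2, depth = 3)
  s <- treeSegments(t3)
  expect_identical(nrow(s), 15L)                       # 2^4 - 1 segments
  expect_identical(sum(!s$id %in% s$parent), 8L)       # 2^3 leaves

  td <- generateVesselTree(3, depth = 2,
                           domain = c(0, 800, 0, 300, 0, 300),
                           compartmentSpec = list(divingDepthRange =
                                                    c(300, 780)))
  deepest <- max(treeSegments(td)$z0, treeSegments(td)$z1)
  expect_gte(deepest, 300)
  expect_lte(deepest, 780)

  expect_error(generateVesselTree(1, 1, domain = c(0, -5, 0, 10, 0, 10)),
               "domain")
})

test_that("trees are deterministic under seed and conserve flow", {
  a <- generateVesselTree(42, depth = 3)
  b <- generateVesselTree(42, depth = 3)
  expect_identical(treeSegments(a), treeSegments(b))

  for (seed in 1:5) {
    s <- treeSegments(generateVesselTree(seed, depth = 3))
    flow <- pi * s$radius^2 * s$speed
    for (p in unique(na.omit(s$parent))) {
      kids <- which(!is.na(s$parent) & s$parent == p)
      expect_lt(abs(sum(flow[kids]) - flow[s$id == p]),
                0.05 * flow[s$id == p])
    }
    idx <- match(s$parent, s$id)
    expect_true(all(is.na(idx) | s$radius <= s$radius[idx] + 1e-9))
  }
})

test_that("capillary beds render thin segments with plausible speeds", {
  bed <- generateCapillaryBed(7, n = 10)
  s <- treeSegments(bed)
  expect_true(all(s$class == "capillary"))
  expect_true(all(s$speed >= 20 & s$speed <= 200))
  tru <- rasterizeTree(bed, acquisitionParams())
  expect_gt(sum(tru$label > 0), 0)  # thin tubes still cover voxels
})

test_that("forward phase model matches the closed form and geometry", {
  p <- acquisitionParams(nTissue = 1.35, dtODT = 2.3e-3)
  oracle <- 4 * pi * 1.35 * 20 * 2.3e-3 / 1.31
  expect_equal(dopplerPhase(20, 0, p), oracle, tolerance = 1e-12)
  expect_equal(dopplerPhase(20, 0, p), 0.596, tolerance = 1e-3)
  expect_equal(dopplerPhase(1e4, 90, p), 0, tolerance = 1e-9)

  ## zero-flow tree, zero noise: phase difference identically 0
  seg <- data.frame(id = 1L, parent = NA_integer_, z0 = 30, x0 = 48, y0 = 5,
                    z1 = 30, x1 = 48, y1 = 90, radius = 6, speed = 0,
                    class = "capillary")
  tree <- vesselTree(seg, domain = c(0, 96, 0, 96, 0, 96))
  acq <- simulateAcquisition(tree, acquisitionParams(nRepeats = 3L),
                             noise = list(speckle = FALSE, additive = 0),
                             seed = 1)
  odt <- phaseSubtractionODT(acq, reconConfig(phaseWindow = c(1L, 1L)))
  expect_true(all(abs(volData(odt)) < 1e-12))
})

test_that("aliasing is synthesized wrapped and flagged, never clipped", {
  p <- acquisitionParams()
  seg <- data.frame(id = 1L, parent = NA_integer_, z0 = 10, x0 = 48, y0 = 5,
                    z1 = 80, x1 = 48, y1 = 20, radius = 6, speed = 500,
                    class = "arteriole")
  tree <- vesselTree(seg, domain = c(0, 96, 0, 96, 0, 96))
  tru <- rasterizeTree(tree, p)
  inV <- tru$label > 0
  expect_true(all(tru$aliased[inV]))
  expect_true(all(abs(tru$dphi[inV]) <= pi + 1e-12))
  raw <- 4 * pi * p@nTissue * tru$vz[inV] * p@dtODT / p@lambda0
  expect_equal(tru$dphi[inV], wrapPhase(raw), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical acquisitions", {
  p <- acquisitionParams(nRepeats = 4L)
  tree <- generateVesselTree(9, 1, domain = c(0, 96, 0, 96, 0, 96))
  a1 <- simulateAcquisition(tree, p, seed = 3)
  a2 <- simulateAcquisition(tree, p, seed = 3)
  expect_identical(acqField(a1), acqField(a2))
})

test_that("bulk motion injection follows the displacement model", {
  fxn <- fxNoiseFree()
  acq <- fxn$acq
  d <- dim(acqField(acq))
  ## zero trace: output equals input exactly
  zero <- motionTrace(matrix(0, d[3], d[4]))
  expect_identical(acqField(injectBulkMotion(acq, zero)), acqField(acq))

  ## delta-z = lambda/(8 n) on one frame: mean phase offset pi/2
  p <- fxn$params
  dz <- matrix(0, d[3], d[4])
  dz[3, 10] <- p@lambda0 / (8 * p@nTissue)
  acqM <- injectBulkMotion(acq, motionTrace(dz), seed = 1)
  f0 <- acqField(acq)[, , 3, 10]
  f1 <- acqField(acqM)[, , 3, 10]
  expect_equal(Arg(mean(Conj(f0) * f1)), pi / 2, tolerance = 0.02)

  ## flagged frames are recorded exactly in the sidecar
  sc <- matrix(FALSE, d[3], d[4])
  withSeed(9, sc[sample.int(d[3] * d[4], 25L)] <- TRUE)
  acqS <- injectBulkMotion(acq, motionTrace(matrix(0, d[3], d[4]), sc),
                           seed = 2)
  expect_identical(acqTruth(acqS)$corrupted, sc)

  ## shape mismatch is a structural error
  expect_error(injectBulkMotion(acq, motionTrace(matrix(0, 2, 2))),
               "shape")
})

test_that("eight scrambled frames at one position are all recorded", {
  fxs <- fxSpeckle()
  d <- dim(acqField(fxs$acq))
  sc <- matrix(FALSE, d[3], d[4])
  withSeed(3, sc[sample.int(14L, 8L), 20L] <- TRUE)
  acqS <- injectBulkMotion(fxs$acq, motionTrace(matrix(0, d[3], d[4]), sc),
                           seed = 1)
  expect_identical(which(acqTruth(acqS)$corrupted[, 20L]), which(sc[, 20L]))
  expect_identical(sum(acqTruth(acqS)$corrupted), 8L)
})

test_that("inter-repeat intensity correlation decreases with scramble amplitude", {
  fxs <- fxSpeckle()
  d <- dim(acqField(fxs$acq))
  sc <- matrix(FALSE, d[3], d[4])
  sc[, 32] <- TRUE
  meanCorr <- vapply(c(0.1, 0.3, 0.6, 1), function(a) {
    acqA <- injectBulkMotion(fxs$acq,
                             motionTrace(matrix(0, d[3], d[4]), sc,
                                         scrambleAmplitude = a), seed = 5)
    f <- Mod(acqField(acqA)[, , , 32])^2
    mean(vapply(seq_len(d[3] - 1L), function(r)
      cor(as.numeric(f[, , r]), as.numeric(f[, , r + 1L])), 1))
  }, 1)
  expect_true(all(diff(meanCorr) < 0))
})
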