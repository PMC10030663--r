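test_that("Hessian orientation recovers cylinder angles within 5 degrees", {
  for (th in c(0, 30, 45, 60, 90)) {
    v <- cylinderVolume(th, n = 48, radius = 4)
    o <- hessianOrientation(v, scales = c(1, 2, 4))
    ctr <- (dim(v) + 1) %/% 2
    est <- o@thetaZ[ctr[1], ctr[2], ctr[3]]
    expect_lte(abs(est - th), 5)
    expect_gt(o@confidence[ctr[1], ctr[2], ctr[3]], 0.5)
  }
  ## isotropic voxels: confidence 0, angle flagged undefined
  flat <- hessianOrientation(array(1, c(16, 16, 16)))
  expect_true(all(is.na(flat@thetaZ)))
  expect_true(all(flat@confidence == 0))
  expect_error(hessianOrientation(cylinderVolume(0), scales = c(-1, 2)),
               "scales")
})

test_that("angle correction applies 1/cos and masks near-horizontal flow", {
  p <- acquisitionParams()
  mk <- function(theta) {
    th <- array(theta, c(2, 2, 2))
    new("OrientationField", thetaZ = th,
        axis = array(0, c(2, 2, 2, 3)),
        confidence = array(1, c(2, 2, 2)))
  }
  odt <- new("ODTVolume", data = array(0.5, c(2, 2, 2)), params = p,
             units = "rad", angleCorrected = FALSE,
             lowConfidence = array(FALSE, c(2, 2, 2)))
  v0 <- volData(angleCorrectVelocity(odt, mk(0)))
  v60 <- volData(angleCorrectVelocity(odt, mk(60)))
  vref <- 0.5 * p@lambda0 / (4 * pi * p@nTissue * p@dtODT)
  expect_equal(v0[1], vref, tolerance = 1e-12)
  expect_equal(v60[1], 2 * vref, tolerance = 1e-12)  # 1/cos(60) = 2
  v89 <- volData(angleCorrectVelocity(odt, mk(89), thetaMax = 80))
  expect_true(all(is.na(v89)))
  expect_error(angleCorrectVelocity(volData(odt), mk(0)), "ODTVolume")
})

test_that("angle-corrected speed is invariant to vessel orientation", {
  p <- acquisitionParams(nRepeats = 4L)
  speeds <- vapply(c(0, 30, 60), function(th) {
    u <- c(cos(th * pi / 180), sin(th * pi / 180), 0)
    len <- 150
    seg <- data.frame(id = 1L, parent = NA_integer_,
                      z0 = 96 - u[1] * len / 2, x0 = 96 - u[2] * len / 2,
                      y0 = 96, z1 = 96 + u[1] * len / 2,
                      x1 = 96 + u[2] * len / 2, y1 = 96, radius = 8,
                      speed = 40, class = "arteriole")
    tree <- vesselTree(seg, domain = c(0, 192, 0, 192, 0, 192))
    acq <- simulateAcquisition(tree, p,
                               noise = list(speckle = FALSE, additive = 0),
                               seed = 1)
    odt <- phaseSubtractionODT(acq, reconConfig(phaseWindow = c(1L, 1L)))
    vel <- angleCorrectVelocity(odt, truthOrientation(acq))
    tru <- acqTruth(acq)
    sel <- homogeneousPhaseVoxels(tru)
    median(abs(volData(vel)[sel]))
  }, 1)
  expect_true(all(abs(speeds - 40) / 40 < 0.03))
})

test_that("branching flow direction labels arterioles and venules", {
  p <- acquisitionParams()
  for (seed in 1:3) {
    gA <- classifyArterioleVenule(
      buildVesselGraph(generateVesselTree(seed, 3), p))
    expect_true(all(graphEdges(gA)$compartment == "arteriole"))
    gV <- classifyArterioleVenule(
      buildVesselGraph(generateVesselTree(seed, 3,
        compartmentSpec = list(flowSense = -1)), p))
    expect_true(all(graphEdges(gV)$compartment == "venule"))
  }
  ## single isolated segment: no topology, no label
  g1 <- classifyArterioleVenule(
    buildVesselGraph(generateVesselTree(3, 0), p))
  expect_identical(graphEdges(g1)$compartment, "unclassified")
})

test_that("classification respects the global flow-sign symmetry", {
  p <- acquisitionParams()
  tree <- generateVesselTree(8, 3)
  g <- buildVesselGraph(tree, p)
  gFlip <- g
  gFlip@edges$signedDoppler <- -g@edges$signedDoppler  # venous counterpart
  lab <- classifyArterioleVenule(g)
  labFlip <- classifyArterioleVenule(gFlip)
  expect_true(all(graphEdges(lab)$compartment == "arteriole"))
  expect_true(all(graphEdges(labFlip)$compartment == "venule"))
})

test_that("small-diameter trees are classified as capillaries", {
  p <- acquisitionParams()
  bed <- generateCapillaryBed(3, n = 6)
  g <- classifyArterioleVenule(buildVesselGraph(bed, p))
  expect_true(all(graphEdges(g)$compartment == "capillary"))
})

test_that("capillary density equals centerline length over area", {
  expect_identical(
    skeletonCapillaryDensity(matrix(FALSE, 40, 40), roi = NULL)$cd, 0)

  p <- acquisitionParams()
  bed <- generateCapillaryBed(7, n = 12, inPlane = TRUE)
  tru <- rasterizeTree(bed, p)
  mask <- apply(tru$label > 0, c(2, 3), any)
  s <- treeSegments(bed)
  L <- sum(sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2))  # in-plane, um
  dens <- skeletonCapillaryDensity(mask, largeVesselCutoff = 10,
                                   pitch = p@voxelPitch[c(2, 3)])
  A <- prod(dim(mask)) * prod(p@voxelPitch[c(2, 3)])
  expect_lt(abs(dens$cd - L / A) / (L / A), 0.1)

  ## identical masks at two time points: no density change
  expect_identical(relativeChange(dens$cd, dens$cd), 0)
})

test_that("capillary density is ROI-translation invariant on homogeneous beds", {
  p <- acquisitionParams()
  bed <- generateCapillaryBed(13, n = 80, domain = c(0, 192, 0, 384, 0, 384),
                              inPlane = TRUE)
  mask <- apply(rasterizeTree(bed, p)$label > 0, c(2, 3), any)
  global <- skeletonCapillaryDensity(mask, pitch = p@voxelPitch[c(2, 3)])$cd
  rois <- list(list(x = c(0, 96), y = c(0, 96)),
               list(x = c(16, 112), y = c(24, 120)),
               list(x = c(32, 128), y = c(32, 128)))
  cds <- vapply(rois, function(roi)
    skeletonCapillaryDensity(mask, roi = roi,
                             pitch = p@voxelPitch[c(2, 3)])$cd, 1)
  ## Poisson sampling error: ~n * (ROI/total area) segments per ROI
  lambda <- 80 * (96 / 128)^2
  expect_true(all(abs(cds - global) / global < 3 / sqrt(lambda)))
  expect_error(skeletonCapillaryDensity(mask,
                                        roi = list(x = c(5, 5),
                                                   y = c(0, 10))), "empty")
})

test_that("diameters come from the distance transform at the centerline", {
  m <- array(FALSE, c(40, 40, 40))
  idx <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  inside <- (idx[, 2] - 20)^2 + (idx[, 3] - 20)^2 <= 25
  m[idx[inside, ]] <- TRUE
  vd <- vesselDiameter(m, points = cbind(9:28, 19, 19))
  expect_lte(abs(vd$mean - 10), 1)   # radius-5 cylinder

  ## identical masks: no diameter change
  expect_identical(relativeChange(vd$mean, vd$mean), 0)
  expect_error(vesselDiameter(m, points = cbind(0L, 0L, 0L)), "off")
})

test_that("a 1.446x dilation is recovered as a ~44.6% diameter change", {
  ## emulates the vasodilation scenario: the same vessel cross-section
  ## dilated by the reported factor
  disk <- function(r) {
    d2 <- outer((1:96 - 48)^2, (1:96 - 48)^2, "+")
    d2 <= r^2
  }
  ctr <- cbind(47L, 47L)  # 0-based centre
  d0 <- vesselDiameter(disk(10), points = ctr)
  d1 <- vesselDiameter(disk(10 * 1.446), points = ctr)
  change <- relativeChange(d0$mean, d1$mean)
  expect_lt(abs(change - 0.446), 0.05)
})

test_that("ROI flow time series yields exact relative changes", {
  p <- acquisitionParams()
  base <- array(0.4, c(10, 10, 10))
  mkv <- function(f) new("ODTVolume", data = base * f, params = p,
                         units = "rad", angleCorrected = FALSE,
                         lowConfidence = array(FALSE, dim(base)))
  vols <- lapply(c(1, 1, 1, 1.5, 1.5), mkv)
  rois <- list(list(name = "r1", compartment = "arteriole",
                    box = list(z = c(0, 10), x = c(0, 10), y = c(0, 10))),
               list(name = "r2", compartment = "arteriole",
                    box = list(z = c(2, 8), x = c(2, 8), y = c(2, 8))))
  ts <- roiFlowTimeseries(vols, rois, baseline = 1:3)
  ser <- tsSeries(ts)
  expect_equal(ser$dcbfv[ser$t <= 3], rep(0, 6), tolerance = 1e-12)
  expect_equal(ser$dcbfv[ser$t > 3], rep(0.5, 4), tolerance = 1e-12)

  ## constant flow: zero change everywhere
  tsc <- roiFlowTimeseries(lapply(c(1, 1, 1), mkv), rois, baseline = 1:2)
  expect_true(all(tsSeries(tsc)$dcbfv == 0))

  ## compartment trace is the arithmetic mean of member ROI traces
  cmp <- tsCompartments(ts)
  for (t in unique(ser$t))
    expect_equal(cmp$mean[cmp$t == t], mean(ser$dcbfv[ser$t == t]),
                 tolerance = 1e-12)

  expect_error(roiFlowTimeseries(vols, list(list(name = "bad",
    compartment = "x", box = list(z = c(0, 99), x = c(0, 10),
                                  y = c(0, 10)))), baseline = 1:2),
    "extent")
  expect_error(roiFlowTimeseries(vols[1], rois, baseline = 1L), "time")
})

test_that("relative-change identities hold exactly", {
  x <- c(0.3, 1, 2.5)
  expect_identical(relativeChange(x, x), c(0, 0, 0))
  expect_identical(relativeChange(x, 2 * x), c(1, 1, 1))
  expect_true(is.na(relativeChange(0.01, 5, floor = 0.05)))
})
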