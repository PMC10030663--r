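test_that("phase subtraction recovers the forward-model phase exactly", {
  fxn <- fxNoiseFree()
  tru <- acqTruth(fxn$acq)
  sel <- homogeneousPhaseVoxels(tru)
  expect_gt(sum(sel), 500)
  err <- abs(volData(fxn$odt)[sel] - tru$dphi[sel]) / abs(tru$dphi[sel])
  expect_lt(max(err), 1e-10)
})

test_that("identical adjacent A-scans give zero phase", {
  withSeed(8, base <- array(complex(real = runif(20 * 2 * 6, 0.5, 2),
                                    imaginary = runif(20 * 2 * 6, -1, 1)),
                            c(20, 2, 6)))
  f <- array(0i, c(20, 8, 2, 6))
  for (x in 1:8) f[, x, , ] <- base
  acq <- new("ComplexAcquisition", field = f, params = acquisitionParams(),
             truth = list(corrupted = matrix(FALSE, 2, 6)))
  odt <- phaseSubtractionODT(acq, reconConfig(phaseWindow = c(1L, 1L)))
  expect_true(all(abs(volData(odt)) < 1e-12))
})

test_that("phase wrapping follows complex-argument arithmetic", {
  ## ground-truth phase pi + 0.1 reconstructs to -pi + 0.1
  eps <- 0.1
  z <- exp(1i * (pi + eps))
  expect_equal(Arg(z), -pi + eps, tolerance = 1e-12)
  p <- acquisitionParams()
  vAlias <- (pi + eps) * p@lambda0 / (4 * pi * p@nTissue * p@dtODT)
  seg <- data.frame(id = 1L, parent = NA_integer_, z0 = 10, x0 = 48, y0 = 5,
                    z1 = 86, x1 = 48, y1 = 5.2, radius = 8, speed = NA,
                    class = "arteriole")
  u <- c(86 - 10, 0, 0.2); u <- u / sqrt(sum(u^2))
  seg$speed <- vAlias / u[1]
  tree <- vesselTree(seg, domain = c(0, 96, 0, 96, 0, 96))
  acq <- simulateAcquisition(tree, p,
                             noise = list(speckle = FALSE, additive = 0),
                             seed = 1)
  tru <- acqTruth(acq)
  odt <- phaseSubtractionODT(acq, reconConfig(phaseWindow = c(1L, 1L)))
  ## homogeneous voxels, aliased ones included this time
  d <- dim(tru$dphi)
  same <- array(FALSE, d)
  same[, 1:(d[2] - 1), ] <- tru$dphi[, 1:(d[2] - 1), ] ==
    tru$dphi[, 2:d[2], ]
  sel <- same & tru$label > 0
  expect_gt(sum(sel & tru$aliased), 100)
  expect_equal(volData(odt)[sel], tru$dphi[sel], tolerance = 1e-9)
  expect_true(all(volData(odt)[sel & tru$aliased] < 0))  # wrapped sign flip
})

test_that("zero-amplitude voxels are flagged low-confidence with phase 0", {
  f <- array(complex(real = 0), c(4, 4, 2, 2))
  acq <- new("ComplexAcquisition", field = f, params = acquisitionParams(),
             truth = list(corrupted = matrix(FALSE, 2, 2)))
  odt <- phaseSubtractionODT(acq, reconConfig(phaseWindow = c(1L, 1L)))
  expect_true(all(volData(odt) == 0))
  expect_true(all(odt@lowConfidence))
})

test_that("frame selection returns all-correlated sets on identical frames", {
  withSeed(1, {
    fr <- array(rexp(32 * 32), c(32, 32, 1))[, , rep(1, 14)]
  })
  sel <- selectCorrelatedBScans(fr, reconConfig())
  expect_length(sel$indices, 6L)
  expect_false(sel$warn)
})

test_that("frame selection recovers exactly the clean frames", {
  fxs <- fxSpeckle()
  d <- dim(acqField(fxs$acq))
  sc <- matrix(FALSE, d[3], d[4])
  withSeed(9, for (y in seq_len(d[4])) sc[sample.int(14L, 8L), y] <- TRUE)
  acqS <- injectBulkMotion(fxs$acq,
                           motionTrace(matrix(0, d[3], d[4]), sc), seed = 3)
  ok <- vapply(seq_len(d[4]), function(y) {
    sel <- selectCorrelatedBScans(Mod(acqField(acqS)[, , , y])^2)
    identical(sel$indices, which(!sc[, y]))
  }, TRUE)
  expect_true(all(ok))
})

test_that("degraded positions fall back to the best two frames with a warning", {
  fxs <- fxSpeckle()
  d <- dim(acqField(fxs$acq))
  sc <- matrix(FALSE, d[3], d[4])
  sc[1:13, 5] <- TRUE  # a single clean frame: no qualifying pair
  acqS <- injectBulkMotion(fxs$acq,
                           motionTrace(matrix(0, d[3], d[4]), sc), seed = 3)
  sel <- selectCorrelatedBScans(Mod(acqField(acqS)[, , , 5])^2)
  expect_length(sel$indices, 2L)
  expect_true(sel$warn)
})

test_that("printed selection defaults round-trip through the config", {
  cfg <- reconConfig()
  expect_identical(cfg@nSelect, 6L)
  expect_identical(cfg@rThreshold, 0.9)
  expect_error(reconConfig(nSelect = 1L))
  expect_error(reconConfig(rThreshold = 1.2))
})

test_that("speckle variance equals brute-force std/mean per voxel", {
  withSeed(1, fr <- array(rexp(20 * 20 * 5), c(20, 20, 5)))
  sv <- speckleVarianceOCA(fr)
  bf <- apply(fr, c(1, 2), sd) / apply(fr, c(1, 2), mean)
  expect_equal(sv, bf, tolerance = 1e-12)

  same <- fr[, , c(1, 1, 1)]
  expect_true(all(speckleVarianceOCA(same) == 0))
  zero <- array(0, c(4, 4, 3))
  expect_true(all(speckleVarianceOCA(zero) == 0))
  expect_error(speckleVarianceOCA(fr[, , 1, drop = FALSE]), "frames")
})

test_that("speckle variance is scale invariant and flow-sensitive", {
  withSeed(2, fr <- array(rexp(16 * 16 * 6), c(16, 16, 6)))
  expect_equal(speckleVarianceOCA(fr * 37.5), speckleVarianceOCA(fr),
               tolerance = 1e-12)

  fxs <- fxSpeckle()
  oca <- reconstructOCA(fxs$acq)
  tru <- acqTruth(fxs$acq)
  lumen <- mean(volData(oca)[tru$label > 0])
  static <- mean(volData(oca)[tru$label == 0])
  expect_gt(lumen, static)
})

test_that("angiography corruption exceeds Doppler corruption for the same motion", {
  ## dt_OCA ~ 100 dt_ODT: a frame-wide axial drift decorrelates the
  ## repeated B-scans but cancels in the lag-1 fast-axis products
  fxs <- fxSpeckle()
  acq <- fxs$acq
  d <- dim(acqField(acq))
  dz <- matrix(0, d[3], d[4])
  withSeed(21, for (y in seq(4, d[4], by = 4))
    dz[, y] <- cumsum(rnorm(d[3], sd = 1.2)))
  acqM <- injectBulkMotion(acq, motionTrace(dz), seed = 7)
  cfg <- reconConfig()
  oca0 <- reconstructOCA(acq, cfg, smooth = NULL)
  ocaM <- reconstructOCA(acqM, cfg, smooth = NULL)
  odt0 <- phaseSubtractionODT(acq, cfg)
  odtM <- phaseSubtractionODT(acqM, cfg)
  corruptFrac <- function(a, b, thr = 0.9) {
    ny <- dim(a)[3]
    mean(vapply(seq_len(ny), function(y)
      cor(as.numeric(a[, , y]), as.numeric(b[, , y])) < thr, TRUE))
  }
  fOCA <- corruptFrac(volData(oca0), volData(ocaM))
  fODT <- corruptFrac(volData(odt0), volData(odtM))
  expect_gt(fOCA, fODT)
})

test_that("frame selection avoids flagged frames whenever enough are clean", {
  fxs <- fxSpeckle()
  d <- dim(acqField(fxs$acq))
  for (nbad in c(2L, 5L, 8L)) {
    sc <- matrix(FALSE, d[3], d[4])
    withSeed(30 + nbad, sc[sample.int(14L, nbad), 10] <- TRUE)
    acqS <- injectBulkMotion(fxs$acq,
                             motionTrace(matrix(0, d[3], d[4]), sc),
                             seed = 3)
    sel <- selectCorrelatedBScans(Mod(acqField(acqS)[, , , 10])^2)
    expect_length(intersect(sel$indices, which(sc[, 10])), 0)
  }
})

test_that("MIP projection takes per-pixel maxima over half-open ranges", {
  v <- array(0, c(6, 5, 4))
  v[3, 2, 4] <- 7
  expect_equal(mipProject(v, "z")[2, 4], 7)
  expect_true(all(mipProject(array(0, c(3, 3, 3))) == 0))

  ramp <- array(rep(1:6, 5 * 4), c(6, 5, 4))
  expect_true(all(mipProject(ramp, "z", c(0, 4)) == 4))  # top of [0, 4)
  expect_true(all(mipProject(ramp, "z") ==
                    apply(ramp, c(2, 3), max)))
  expect_error(mipProject(ramp, "z", c(2, 2)), "empty")
  expect_error(mipProject(ramp, "z", c(0, 9)), "extent")
})

test_that("ratio images implement (b - a)/a with a magnitude floor", {
  withSeed(4, a <- array(runif(5^3, 0.2, 2), c(5, 5, 5)))
  expect_true(all(ratioImage(a, a, floor = 0.1) == 0))
  expect_equal(ratioImage(a, 1.5 * a, floor = 0.1),
               array(0.5, dim(a)), tolerance = 1e-12)
  b <- a
  a[1, 1, 1] <- 1e-6
  r <- ratioImage(a, b, floor = 0.05)
  expect_true(is.na(r[1, 1, 1]))
  expect_false(any(is.infinite(r), na.rm = TRUE))

  p <- acquisitionParams()
  va <- new("ODTVolume", data = array(0.5, c(2, 2, 2)), params = p,
            units = "rad", angleCorrected = FALSE,
            lowConfidence = array(FALSE, c(2, 2, 2)))
  vb <- new("ODTVolume", data = array(0.5, c(2, 2, 2)), params = p,
            units = "um/s", angleCorrected = TRUE,
            lowConfidence = array(FALSE, c(2, 2, 2)))
  expect_error(ratioImage(va, vb), "unit")
})
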