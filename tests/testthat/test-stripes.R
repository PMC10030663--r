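test_that("stripe detection finds injected bands and nothing on clean input", {
  fxp <- fxStripePath()
  sm <- fxp$stripes
  b <- stripeBands(sm)
  injected <- unlist(fxp$bands) - 1L  # 0-based positions
  covered <- unlist(lapply(seq_len(nrow(b)), function(i)
    seq.int(b[i, 1], b[i, 2] - 1L)))
  expect_gte(mean(injected %in% covered), 0.95)
  ## no band is disjoint from the injected positions (no false bands)
  for (i in seq_len(nrow(b)))
    expect_gt(length(intersect(seq.int(b[i, 1], b[i, 2] - 1L),
                               injected)), 0)

  clean <- detectStripes(mipProject(reconstructOCA(fxp$acq)))
  expect_identical(nrow(stripeBands(clean)), 0L)
})

test_that("the detection statistic grows with scramble amplitude below saturation", {
  fxs <- fxSpeckle()
  d <- dim(acqField(fxs$acq))
  sc <- matrix(FALSE, d[3], d[4])
  bandPos <- 30:35
  withSeed(4, for (y in bandPos) sc[sample.int(14L, 13L), y] <- TRUE)
  ## the statistic saturates once frames are fully decorrelated, so the
  ## sweep probes the onset regime
  stats <- vapply(c(0.1, 0.2, 0.3), function(a) {
    acqA <- injectBulkMotion(fxs$acq,
                             motionTrace(matrix(0, d[3], d[4]), sc,
                                         scrambleAmplitude = a), seed = 5)
    z <- stripeZScores(mipProject(reconstructOCA(acqA)))
    mean(z[bandPos])
  }, 1)
  expect_true(all(diff(stats) > 0))
})

test_that("oriented flux responds to tubes at the right scale", {
  expect_true(all(oofVesselness(matrix(1, 32, 32),
                                radii = c(2, 3))$response == 0))

  img <- matrix(0, 64, 64)
  img[, abs(seq_len(64) - 32) <= 4] <- 1   # bright band of radius 4 px
  oof <- oofVesselness(img, radii = 2:6)
  expect_true(oof$scale[30, 32] %in% 3:5)

  expect_error(oofVesselness(img, radii = c(2, 40)), "radii")
  expect_error(oofVesselness(img, radii = numeric(0)), "radii")
})

test_that("centerline response beats background at moderate SNR", {
  withSeed(6, {
    img <- matrix(rnorm(64 * 64, sd = 1 / 3), 64, 64)  # SNR 3
    img[, abs(seq_len(64) - 32) <= 3] <-
      img[, abs(seq_len(64) - 32) <= 3] + 1
  })
  r <- oofVesselness(img, radii = c(2, 3, 4))$response
  expect_gt(mean(r[, 30:34]), mean(r[, c(1:20, 45:64)]))
})

test_that("binarization yields a clean {0,1} mask with hysteresis", {
  withSeed(7, {
    img <- matrix(rnorm(64 * 64, sd = 0.2), 64, 64)    # SNR 5 tube
    img[, abs(seq_len(64) - 32) <= 3] <-
      img[, abs(seq_len(64) - 32) <= 3] + 1
  })
  truth <- matrix(FALSE, 64, 64)
  truth[, abs(seq_len(64) - 32) <= 3] <- TRUE
  mask <- binarizeVesselness(oofVesselness(img, radii = c(2, 3, 4))$response)
  m <- maskArray(mask)
  expect_true(all(m %in% c(TRUE, FALSE)))
  expect_identical(sum(m), sum(m == TRUE))
  expect_gte(diceOverlap(m, truth), 0.8)

  expect_warning(em <- binarizeVesselness(matrix(1, 16, 16)), "degenerate")
  expect_false(any(maskArray(em)))
  bg <- suppressWarnings(
    binarizeVesselness(oofVesselness(matrix(0, 32, 32),
                                     radii = c(2, 3))$response))
  expect_false(any(maskArray(bg)))
})

test_that("no stripe bands are reported on clean phantoms over many seeds", {
  params <- acquisitionParams()
  for (seed in 1:20) {
    tree <- generateVesselTree(seed, 2, domain = c(0, 192, 0, 192, 0, 192))
    acq <- simulateAcquisition(tree, params, noise = list(), seed = seed)
    sm <- detectStripes(mipProject(reconstructOCA(acq)))
    expect_identical(nrow(stripeBands(sm)), 0L)
  }
})
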