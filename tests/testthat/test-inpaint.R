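test_that("training pairs are deterministic and match the stripe widths", {
  fxp <- fxStripePath()
  p1 <- makeInpaintTrainingPairs(fxp$mask, fxp$mip, fxp$stripes, n = 30L,
                                 seed = 7)
  p2 <- makeInpaintTrainingPairs(fxp$mask, fxp$mip, fxp$stripes, n = 30L,
                                 seed = 7)
  expect_identical(p1, p2)

  ## stripe width 0: input mask channel equals the target everywhere
  p0 <- makeInpaintTrainingPairs(fxp$mask, fxp$mip, NULL, n = 5L,
                                 widthRange = c(0, 0), seed = 1)
  for (pr in p0) {
    expect_identical(pr$input[, , 1], pr$target)
    expect_false(any(pr$occluded))
  }

  ## occluded fraction per patch matches the drawn stripe width exactly,
  ## and the aggregate matches the log-uniform width distribution
  many <- makeInpaintTrainingPairs(fxp$mask, fxp$mip, fxp$stripes, n = 200L,
                                  seed = 11)
  widths <- vapply(many, function(pr) sum(pr$occluded), 1L)
  for (pr in many)
    expect_equal(mean(pr$weight == 1), sum(pr$occluded) / 64,
                 tolerance = 1e-12)
  expect_true(all(widths >= 4L & widths <= 32L))
  expectedMean <- (32 - 4) / log(32 / 4)   # mean of the log-uniform draw
  expect_lt(abs(mean(widths) - expectedMean) / expectedMean, 0.1)
})

test_that("training reduces the inpainting loss well below initialization", {
  fxp <- fxStripePath()
  mf <- modelManifest(fxp$model)
  expect_lt(mf$finalLoss, 0.5 * mf$initLoss)
  expect_true(all(is.finite(mf$losses)))
})

test_that("training is deterministic under a fixed seed", {
  fxp <- fxStripePath()
  short <- trainInpainting(fxp$pairs[1:20], list(iterations = 15L, seed = 3))
  again <- trainInpainting(fxp$pairs[1:20], list(iterations = 15L, seed = 3))
  expect_identical(modelManifest(short), modelManifest(again))
  expect_identical(short@params, again@params)
  expect_error(trainInpainting(list(), list(iterations = 1L)), "pair")
})

test_that("inpainting is identity outside stripes and empty stripes are a no-op", {
  fxp <- fxStripePath()
  none <- stripeMask(nSlow = ncol(fxp$mip))
  expect_identical(inpaintStripes(fxp$mask, none, fxp$model, fxp$mip),
                   fxp$mask)

  b <- stripeBands(fxp$stripes)
  bandCols <- unlist(lapply(seq_len(nrow(b)), function(i)
    (b[i, 1] + 1):b[i, 2]))
  expect_identical(maskArray(fxp$filled)[, -bandCols],
                   maskArray(fxp$mask)[, -bandCols])
  expect_true(all(which(apply(inpaintedArray(fxp$filled), 2, any))
                  %in% bandCols))

  untrained <- new("ConvModel", kind = "inpaint2d", params = list(),
                   config = list(), manifest = list(), trained = FALSE)
  expect_error(inpaintStripes(fxp$mask, fxp$stripes, untrained, fxp$mip),
               "trained")
})

test_that("a straight vessel severed by a stripe regains connectivity", {
  fxv <- fxStraightVessel()
  sev <- fxv$truthMask
  sev[, fxv$stripe] <- FALSE
  expect_identical(skeletonComponents(sev), 2L)
  expect_identical(skeletonComponents(maskArray(fxv$filled)), 1L)
})

test_that("the full stripe path raises vessel-mask Dice substantially", {
  fxp <- fxStripePath()
  d0 <- diceOverlap(maskArray(fxp$maskRaw), fxp$truthMask)
  d1 <- diceOverlap(maskArray(fxp$filled), fxp$truthMask)
  expect_gte(d1 - d0, 0.15)
})

test_that("mask multiplication zeroes background and is idempotent", {
  fxp <- fxStripePath()
  enh <- enhanceOCA(fxp$mip, fxp$filled)
  m <- maskArray(fxp$filled)
  expect_true(all(enh[!m] == 0))
  expect_identical(enh[m], fxp$mip[m])          # foreground unchanged
  expect_identical(enhanceOCA(enh, fxp$filled), enh)

  ones <- vesselnessMask(matrix(TRUE, nrow(fxp$mip), ncol(fxp$mip)))
  expect_equal(enhanceOCA(fxp$mip, ones), fxp$mip * 1, tolerance = 1e-15)
  zeros <- vesselnessMask(matrix(FALSE, nrow(fxp$mip), ncol(fxp$mip)))
  expect_true(all(enhanceOCA(fxp$mip, zeros) == 0))
  expect_error(enhanceOCA(fxp$mip[1:10, ], fxp$filled), "shape")
})
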