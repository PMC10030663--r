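test_that("intensity remapping is monotone, rank-preserving and seeded", {
  withSeed(3, v <- array(abs(rnorm(20^3)), c(20, 20, 20)))
  spec <- augmentationSpec(seed = 5L)
  mask <- v > quantile(v, 0.8)

  ## identity control points leave the volume unchanged
  idv <- intensityRemap(v, spec, mask = mask,
                        controlPoints = list(x = c(0, 5), y = c(0, 5)))
  expect_identical(idv, v)

  r1 <- intensityRemap(v, spec, mask = mask, seed = 9)
  r2 <- intensityRemap(v, spec, mask = mask, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(r1, v))
  expect_identical(r1[!mask], v[!mask])      # only vessel voxels remapped
  expect_equal(cor(r1[mask], v[mask], method = "spearman"), 1)

  expect_error(intensityRemap(v, spec,
                              controlPoints = list(x = c(0, 1, 0.5),
                                                   y = c(0, 1, 2))),
               "monotone")
})

test_that("vessel cropping drops the requested fraction with an exact record", {
  withSeed(4, v <- array(abs(rnorm(30^3)), c(30, 30, 30)))
  mask <- array(FALSE, dim(v))
  mask[12:18, 5:26, 14:16] <- TRUE

  spec0 <- augmentationSpec(cropFraction = 0)
  out0 <- vesselCrop(v, mask, spec0)
  expect_identical(out0$volume, v)
  expect_length(out0$record, 0L)

  spec <- augmentationSpec(cropFraction = 0.3, seed = 2L)
  out <- vesselCrop(v, mask, spec)
  frac <- length(out$record) / sum(mask)
  expect_gte(frac, 0.2)
  expect_lte(frac, 0.4)
  ## record + surviving vessel voxels partition the original vessel voxels
  surviving <- setdiff(which(mask), out$record)
  expect_identical(sort(c(out$record, surviving)), which(mask))
  expect_true(all(out$record %in% which(mask)))
  ## voxels outside the record untouched
  keep <- setdiff(seq_along(v), out$record)
  expect_identical(out$volume[keep], v[keep])

  tiny <- array(FALSE, dim(v)); tiny[15, 15, 15] <- TRUE
  expect_error(vesselCrop(v, tiny, augmentationSpec(cropFraction = 0.6)),
               "segment")
  expect_error(vesselCrop(v, array(FALSE, dim(v)), spec), "empty")
})

test_that("enhancer training is deterministic and needs no clean targets", {
  withSeed(5, v <- array(abs(rnorm(48^3, sd = 0.3)), c(48, 48, 48)))
  v[20:28, 10:38, 22:26] <- v[20:28, 10:38, 22:26] + 1.5
  spec <- augmentationSpec(seed = 1L)
  cfg <- list(iterations = 6L, patch = 24L, seed = 2L)
  m1 <- trainEnhancer(list(v), spec, cfg)
  m2 <- trainEnhancer(list(v), spec, cfg)
  expect_identical(modelManifest(m1), modelManifest(m2))
  expect_identical(m1@params, m2@params)
  ## the training interface consumes single noisy volumes only: there is no
  ## argument through which a clean target could be supplied
  expect_false(any(grepl("clean|target|reference",
                         names(formals(trainEnhancer)))))
  expect_error(trainEnhancer(list(), spec), "volume")
})

test_that("autoencoding degenerates gracefully with no crop and identity remap", {
  withSeed(6, v <- array(abs(rnorm(48^3, sd = 0.3)), c(48, 48, 48)))
  v[20:28, 10:38, 22:26] <- v[20:28, 10:38, 22:26] + 1.5
  spec <- augmentationSpec(cropFraction = 0, nControl = 0L, noiseSD = 0.15,
                           seed = 1L)
  m <- trainEnhancer(list(v), spec, list(iterations = 60L, patch = 24L,
                                         seed = 1L))
  mf <- modelManifest(m)
  expect_lt(mf$finalLoss, mf$initLoss)
})

test_that("desk-scale training reaches the reference loss reduction", {
  fxe <- fxEnhance()
  mf <- modelManifest(fxe$model)
  expect_lt(mf$finalLoss, 0.6 * mf$initLoss)
})

test_that("enhancement raises CNR and restores connectivity", {
  fxe <- fxEnhance()
  a0 <- abs(volData(fxe$odt))
  a1 <- abs(volData(fxe$enh))
  vm <- fxe$vesselMask
  expect_gt(cnrOf(a1, vm), cnrOf(a0, vm))

  nTrue <- ccCount(vm)
  cc0 <- ccCount(maskArray(binarizeVesselness(
    oofVesselness(a0, c(1.5, 2.5))$response)))
  cc1 <- ccCount(maskArray(binarizeVesselness(
    oofVesselness(a1, c(1.5, 2.5))$response)))
  expect_lt(abs(cc1 - nTrue), abs(cc0 - nTrue))
})

test_that("enhancement operates on magnitude and never flips flow sign", {
  fxe <- fxEnhance()
  s0 <- sign(volData(fxe$odt))
  s1 <- sign(volData(fxe$enh))
  expect_true(all(s1 == 0 | s1 == s0))
  expect_true(all(is.finite(volData(fxe$enh))))
  expect_identical(dim(volData(fxe$enh)), dim(volData(fxe$odt)))

  expect_error(enhanceVolume(array(0, c(8, 8, 8)), fxe$model),
               "receptive|smaller")
  untrained <- new("ConvModel", kind = "enhance3d", params = list(),
                   config = list(), manifest = list(), trained = FALSE)
  expect_error(enhanceVolume(fxe$odt, untrained), "trained")
})

test_that("training learns intensity-invariant features", {
  fxe <- fxEnhance()
  v <- abs(volData(fxe$odt))
  mask <- fxe$vesselMask
  rm1 <- intensityRemap(v, fxe$spec, mask = mask, seed = 77)
  e0 <- abs(volData(enhanceVolume(fxe$odt, fxe$model)))
  o1 <- fxe$odt; o1@data <- rm1
  e1 <- abs(volData(enhanceVolume(o1, fxe$model)))
  expect_gte(cor(e0[mask], e1[mask]), 0.8)
})

test_that("dropped segments are substantially restored after training", {
  fxe <- fxEnhance()
  nz <- modelManifest(fxe$model)$normalization
  vN <- (abs(volData(fxe$odt)) - nz[["p1"]]) / (nz[["p99"]] - nz[["p1"]])
  crop <- vesselCrop(vN, fxe$vesselMask,
                     augmentationSpec(cropFraction = 0.3, seed = 12),
                     seed = 12)
  cropped <- fxe$odt
  cropped@data <- crop$volume * (nz[["p99"]] - nz[["p1"]]) + nz[["p1"]]
  enh <- enhanceVolume(cropped, fxe$model)
  resp <- oofVesselness(abs(volData(enh)), c(1.5, 2.5))$response
  thr <- quantile(resp[resp > 0], 0.85)
  expect_gte(mean(resp[crop$record] >= thr), 0.6)
})
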