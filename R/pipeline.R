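## Pipeline driver: validated configuration, seed fan-out, stage execution
## in dependency order and a reproducibility manifest.

#' Default pipeline configuration
#'
#' A nested list covering every stage with desk-scale defaults; it doubles
#' as the validation schema (unknown keys are rejected). The preset knob of
#' the phantom stage chooses the motion regime: "anesthetized" injects no
#' motion, "awake" scrambles a random subset of frames at a few slow-axis
#' bands, "chronic" uses a milder trace.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outDir = "octflow-run",
    quiet = FALSE,
    stages = list(phantom = TRUE, recon = TRUE, denoiseOCA = TRUE,
                  denoiseODT = TRUE, quant = TRUE),
    phantom = list(
      preset = "awake", depth = 3L, domainSize = 192,
      noise = list(speckle = TRUE, lumenContrast = 3, additive = 0.05,
                   phaseNoise = 0.15, decorrLength = 10),
      nRepeats = 14L, dtODT = 2.3e-3, dtOCA = 0.21,
      rootSpeed = 80, rootRadius = 10
    ),
    recon = list(nSelect = 6L, rThreshold = 0.9, phaseWindow = c(3L, 3L)),
    denoiseOCA = list(zThreshold = 6, oofRadii = c(1.5, 2.5, 4),
                      trainPairs = 120L, iterations = 300L, patch = 64L,
                      widthRange = c(4, 32)),
    denoiseODT = list(iterations = 200L, patch = 32L, cropFraction = 0.3,
                      noiseSD = 0.05),
    quant = list(capillaryCutoff = 10, thetaMax = 80,
                 orientationScales = c(1, 2, 4))
  )
}

validateConfig <- function(config, schema = defaultPipelineConfig(),
                           path = "config") {
  extra <- setdiff(names(config), names(schema))
  if (length(extra))
    stop("unknown configuration key(s) under ", path, ": ",
         paste(extra, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]])) &&
        is.list(config[[nm]]))
      validateConfig(config[[nm]], schema[[nm]], paste0(path, "$", nm))
  }
  modifyList(schema, config)
}

pipelineLog <- function(quiet, stage, ...) {
  if (!quiet)
    message(sprintf("[octflow:%s] %s", stage, paste0(...)))
}

motionTraceForPreset <- function(preset, nr, ny, seed) {
  withSeed(seed, {
    dz <- matrix(0, nr, ny)
    sc <- matrix(FALSE, nr, ny)
    if (preset != "anesthetized") {
      nBands <- if (preset == "awake") 3L else 1L
      starts <- sort(sample.int(ny - 8L, nBands))
      for (s in starts) {
        w <- sample(4:7, 1L)
        ys <- s:min(ny, s + w - 1L)
        nScr <- if (preset == "awake") nr - 1L else nr %/% 2L
        for (y in ys) {
          sc[sample.int(nr, nScr), y] <- TRUE
          dz[, y] <- cumsum(rnorm(nr, sd = 0.15))
        }
      }
    }
    motionTrace(dz, sc, scrambleAmplitude = if (preset == "chronic") 0.6
                                            else 1)
  })
}

#' Run the full reconstruction/denoising/quantification pipeline
#'
#' Stages execute in dependency order (phantom, reconstruction, angiography
#' denoising, Doppler enhancement, quantification); each stage writes its
#' outputs under the run directory and registers them, with checksums, in
#' the run manifest. One global seed fans out to per-stage seeds by stable
#' hashing of the stage name. A failing stage leaves the outputs of prior
#' stages intact and is recorded in the manifest.
#'
#' @param config nested list (see \code{\link{defaultPipelineConfig}}) or a
#'   path to a YAML file with the same structure.
#' @return the run manifest (invisibly also written to manifest.json).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cf <- validateConfig(config)
  dir.create(cf$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(configHash = hashObject(cf), seed = cf$seed,
                   package = as.character(utils::packageVersion("octflow")),
                   stages = list())
  state <- new.env(parent = emptyenv())
  addStage <- function(name, outputs, t0) {
    manifest$stages[[name]] <<- list(
      seed = stageSeed(cf$seed, name),
      outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                                 basename(outputs))),
      elapsed = round(as.numeric(Sys.time()) - t0, 3))
  }
  runStage <- function(name, enabled, fn) {
    if (!enabled) return(invisible(NULL))
    t0 <- as.numeric(Sys.time())
    pipelineLog(cf$quiet, name, "start (seed ",
                stageSeed(cf$seed, name), ")")
    out <- tryCatch(fn(stageSeed(cf$seed, name)), error = function(e) e)
    if (inherits(out, "error")) {
      manifest$stages[[name]] <<- list(failed = conditionMessage(out))
      writeManifest(manifest, cf$outDir)
      stop("stage '", name, "' failed: ", conditionMessage(out))
    }
    addStage(name, out, t0)
    pipelineLog(cf$quiet, name, "done (",
                manifest$stages[[name]]$elapsed, " s)")
  }

  runStage("phantom", cf$stages$phantom, function(seed) {
    ph <- cf$phantom
    dsz <- ph$domainSize
    params <- acquisitionParams(dtODT = ph$dtODT, dtOCA = ph$dtOCA,
                                nRepeats = ph$nRepeats)
    ## slow axis twice the fast axis so the inpainting patches always find
    ## clean regions between motion bands
    tree <- generateVesselTree(seed, depth = ph$depth,
                               domain = c(0, dsz, 0, dsz, 0, 2 * dsz),
                               compartmentSpec = list(
                                 rootSpeed = ph$rootSpeed,
                                 rootRadius = ph$rootRadius))
    acq <- simulateAcquisition(tree, params, noise = ph$noise, seed = seed)
    ny <- dim(acq@field)[4]
    trace <- motionTraceForPreset(ph$preset, params@nRepeats, ny,
                                  seed + 1L)
    acq <- injectBulkMotion(acq, trace, seed = seed + 2L)
    adir <- file.path(cf$outDir, "acquisition")
    saveAcquisition(acq, adir)
    writeTreeJSON(tree, file.path(cf$outDir, "tree.json"))
    state$acq <- acq
    state$tree <- tree
    state$params <- params
    c(list.files(adir, full.names = TRUE),
      file.path(cf$outDir, "tree.json"))
  })

  runStage("recon", cf$stages$recon, function(seed) {
    rc <- reconConfig(cf$recon$nSelect, cf$recon$rThreshold,
                      cf$recon$phaseWindow)
    state$odt <- phaseSubtractionODT(state$acq, rc)
    state$oca <- reconstructOCA(state$acq, rc)
    p <- state$params@voxelPitch
    f1 <- file.path(cf$outDir, "odt.nii.gz")
    f2 <- file.path(cf$outDir, "oca.nii.gz")
    f3 <- file.path(cf$outDir, "oca_mip.tiff")
    writeVolume(state$odt@data, f1, p)
    writeVolume(state$oca@data, f2, p)
    writeMIPTiff(mipProject(state$oca), f3)
    c(f1, f2, f3)
  })

  runStage("denoiseOCA", cf$stages$denoiseOCA, function(seed) {
    dn <- cf$denoiseOCA
    mip <- mipProject(state$oca)
    stripes <- detectStripes(mip, list(zThreshold = dn$zThreshold))
    oof <- oofVesselness(mip, dn$oofRadii)
    mask <- binarizeVesselness(oof$response, list(stripes = stripes))
    pairs <- makeInpaintTrainingPairs(mask, mip, stripes,
                                      n = dn$trainPairs, patch = dn$patch,
                                      widthRange = dn$widthRange,
                                      seed = seed)
    model <- trainInpainting(pairs, list(iterations = dn$iterations,
                                         seed = seed))
    filled <- inpaintStripes(mask, stripes, model, mip, patch = dn$patch)
    enh <- enhanceOCA(mip, filled)
    f <- c(file.path(cf$outDir, "oca_mask.tiff"),
           file.path(cf$outDir, "oca_mask_inpainted.tiff"),
           file.path(cf$outDir, "oca_enhanced.tiff"),
           file.path(cf$outDir, "stripes.csv"),
           file.path(cf$outDir, "inpaint_model.json"))
    writeMaskTiff(mask, f[1])
    writeMaskTiff(filled, f[2])
    writeMIPTiff(enh, f[3])
    b <- stripeBands(stripes)
    utils::write.csv(data.frame(start = b[, 1], end = b[, 2],
                                score = stripes@scores), f[4],
                     row.names = FALSE)
    saveModel(model, f[5])
    state$ocaMask <- filled
    state$ocaEnhanced <- enh
    f
  })

  runStage("denoiseODT", cf$stages$denoiseODT, function(seed) {
    dn <- cf$denoiseODT
    spec <- augmentationSpec(cropFraction = dn$cropFraction,
                             noiseSD = dn$noiseSD, seed = seed)
    model <- trainEnhancer(list(state$odt), spec,
                           list(iterations = dn$iterations,
                                patch = dn$patch, seed = seed))
    state$odtEnhanced <- enhanceVolume(state$odt, model)
    f <- c(file.path(cf$outDir, "odt_enhanced.nii.gz"),
           file.path(cf$outDir, "enhance_model.json"))
    writeVolume(state$odtEnhanced@data, f[1], state$params@voxelPitch)
    saveModel(model, f[2])
    f
  })

  runStage("quant", cf$stages$quant, function(seed) {
    q <- cf$quant
    odt <- if (!is.null(state$odtEnhanced)) state$odtEnhanced else state$odt
    orient <- hessianOrientation(odt, scales = q$orientationScales)
    vel <- angleCorrectVelocity(odt, orient, thetaMax = q$thetaMax)
    graph <- buildVesselGraph(state$tree, state$params, odt = odt)
    graph <- classifyArterioleVenule(graph,
                                     capillaryCutoff = q$capillaryCutoff)
    mask2d <- if (!is.null(state$ocaMask)) state$ocaMask else
      binarizeVesselness(oofVesselness(mipProject(state$oca),
                                       c(1.5, 2.5, 4))$response)
    px <- state$params@voxelPitch[c(2, 3)]
    dens <- skeletonCapillaryDensity(mask2d,
                                     largeVesselCutoff = q$capillaryCutoff,
                                     pitch = px)
    f <- c(file.path(cf$outDir, "velocity.nii.gz"),
           file.path(cf$outDir, "graph.graphml"),
           file.path(cf$outDir, "graph_edges.csv"),
           file.path(cf$outDir, "density.csv"))
    writeVolume(ifelse(is.na(vel@data), 0, vel@data), f[1],
                state$params@voxelPitch)
    writeVesselGraph(graph, file.path(cf$outDir, "graph"))
    utils::write.csv(data.frame(cd = dens$cd,
                                skeletonLength = dens$skeletonLength,
                                roiArea = dens$roiArea,
                                fillFactor = dens$fillFactor),
                     f[4], row.names = FALSE)
    f
  })

  writeManifest(manifest, cf$outDir)
  invisible(manifest)
}

writeManifest <- function(manifest, outDir) {
  tmp <- file.path(outDir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(outDir, "manifest.json"))
  invisible(NULL)
}
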