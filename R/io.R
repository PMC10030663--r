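## Readers/writers for the volume formats used by the pipeline: NIfTI
## (float volumes + truth sidecars), multi-page TIFF (stacks, 16-bit MIPs),
## JSON (trees, ROIs, models, manifests).

#' Read a volume from NIfTI or TIFF
#'
#' Axis order is normalized to the package grid convention (z, x, y) from a
#' declared \code{axes} permutation (e.g. "yxz" when TIFF pages are y
#' slices). Missing pitch metadata yields unit voxels with a warning.
#'
#' @param path file path (.nii/.nii.gz or .tif/.tiff).
#' @param axes three-letter permutation naming the on-disk axis order.
#' @return list: data (array, z-x-y), pitch (um, NA when unknown).
#' @export
readVolume <- function(path, axes = "zxy") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    pitch <- attr(img, "pixdim")[seq_len(min(3L, length(dim(arr))))]
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    ## pages stack along the last declared axis; page rows/cols are the
    ## first two
    pitch <- rep(NA_real_, 3)
  } else stop("unsupported format: ", ext)
  perm <- match(c("z", "x", "y"), strsplit(axes, "")[[1]])
  if (length(dim(arr)) == 3L && any(is.na(perm)))
    stop("axes must be a permutation of z, x, y")
  if (length(dim(arr)) == 3L && !identical(perm, 1:3)) {
    arr <- aperm(arr, perm)
    pitch <- pitch[perm]
  }
  if (any(is.na(pitch))) {
    warning("missing pitch metadata; assuming unit voxels")
    pitch <- rep(1, 3)
  }
  list(data = arr, pitch = pitch)
}

#' Write a volume as float32 NIfTI
#'
#' @param data numeric array (z, x, y order).
#' @param path output path (.nii or .nii.gz).
#' @param pitch voxel pitch, um.
#' @export
writeVolume <- function(data, path, pitch = c(1, 1, 1)) {
  attr(data, "pixdim") <- unname(pitch[seq_len(min(3L, length(dim(data))))])
  img <- RNifti::asNifti(data, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an en-face image as 16-bit TIFF
#'
#' Values are linearly scaled to the full 16-bit range (the scale is
#' returned invisibly).
#'
#' @param img numeric matrix.
#' @param path output path.
#' @export
writeMIPTiff <- function(img, path) {
  hi <- max(img)
  sc <- if (hi > 0) img / hi else img
  tiff::writeTIFF(sc, path, bits.per.sample = 16L)
  invisible(hi)
}

#' Write a binary mask as 8-bit TIFF
#' @param mask logical matrix or \linkS4class{VesselnessMask}.
#' @param path output path.
#' @export
writeMaskTiff <- function(mask, path) {
  m <- if (is(mask, "VesselnessMask")) maskArray(mask) else mask
  tiff::writeTIFF(m * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Save / load a complex acquisition as paired real/imag NIfTI volumes
#'
#' The complex field is stored as two 4D float volumes plus a JSON sidecar
#' for the acquisition parameters and NIfTI/JSON files for the ground
#' truth.
#'
#' @param acq a \linkS4class{ComplexAcquisition}.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
saveAcquisition <- function(acq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- acq@params
  writeVolume(Re(acq@field), file.path(dir, "field_real.nii.gz"),
              p@voxelPitch)
  writeVolume(Im(acq@field), file.path(dir, "field_imag.nii.gz"),
              p@voxelPitch)
  for (nm in c("label", "compartment", "speed", "vz", "thetaZ", "dphi")) {
    a <- acq@truth[[nm]]
    a[is.na(a)] <- -1
    writeVolume(a, file.path(dir, paste0("truth_", nm, ".nii.gz")),
                p@voxelPitch)
  }
  writeVolume(acq@truth$aliased * 1,
              file.path(dir, "truth_aliased.nii.gz"), p@voxelPitch)
  meta <- list(
    params = list(lambda0 = p@lambda0, deltaLambda = p@deltaLambda,
                  nTissue = p@nTissue, dtODT = p@dtODT, dtOCA = p@dtOCA,
                  nRepeats = p@nRepeats, voxelPitch = unname(p@voxelPitch),
                  axialPSF = p@axialPSF),
    corrupted = which(acq@truth$corrupted, arr.ind = TRUE)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveAcquisition
#' @param dir the directory written by \code{saveAcquisition}.
#' @export
loadAcquisition <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pm <- meta$params
  params <- acquisitionParams(lambda0 = pm$lambda0,
                              deltaLambda = pm$deltaLambda,
                              nTissue = pm$nTissue, dtODT = pm$dtODT,
                              dtOCA = pm$dtOCA, nRepeats = pm$nRepeats,
                              voxelPitch = pm$voxelPitch,
                              axialPSF = pm$axialPSF)
  re <- readVolume(file.path(dir, "field_real.nii.gz"))$data
  im <- readVolume(file.path(dir, "field_imag.nii.gz"))$data
  field <- array(complex(real = re, imaginary = im), dim(re))
  truth <- list()
  for (nm in c("label", "compartment", "speed", "vz", "thetaZ", "dphi"))
    truth[[nm]] <- readVolume(file.path(dir,
                                        paste0("truth_", nm, ".nii.gz")))$data
  truth$thetaZ[truth$thetaZ < 0] <- NA_real_
  truth$label <- array(as.integer(round(truth$label)), dim(truth$label))
  truth$aliased <- array(
    readVolume(file.path(dir, "truth_aliased.nii.gz"))$data > 0.5,
    dim(truth$label))
  corr <- matrix(FALSE, dim(field)[3], dim(field)[4])
  ci <- meta$corrupted
  if (length(ci)) corr[as.matrix(ci)] <- TRUE
  truth$corrupted <- corr
  new("ComplexAcquisition", field = field, params = params, truth = truth)
}

#' Serialize / restore a vessel tree as JSON
#' @param tree a \linkS4class{VesselTree}.
#' @param path file path.
#' @export
writeTreeJSON <- function(tree, path) {
  jsonlite::write_json(list(segments = tree@segments,
                            flowSense = tree@flowSense,
                            domain = tree@domain),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTreeJSON
#' @export
readTreeJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- as.data.frame(x$segments)
  if (is.null(seg$parent)) seg$parent <- NA_integer_
  seg$parent <- as.integer(seg$parent)
  seg$id <- as.integer(seg$id)
  cols <- c("id", "parent", "z0", "x0", "y0", "z1", "x1", "y1", "radius",
            "speed", "class")
  vesselTree(seg[, cols], flowSense = as.numeric(x$flowSense),
             domain = as.numeric(x$domain))
}

#' Read ROI definitions from JSON
#'
#' Schema: an array of objects with name, compartment and box, where box
#' holds half-open 0-based voxel intervals z, x, y.
#'
#' @param path JSON file.
#' @return list of ROI lists as consumed by
#'   \code{\link{roiFlowTimeseries}}.
#' @export
readROIs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(r) list(name = r$name, compartment = r$compartment,
                             box = lapply(r$box, unlist)))
}

#' Save / load a trained model (weights + manifest) as JSON
#'
#' The serialization carries a format version header, the architecture
#' config, the full training manifest and every weight array with its
#' dimensions.
#'
#' @param model a \linkS4class{ConvModel}.
#' @param path output path (.json).
#' @export
saveModel <- function(model, path) {
  ser <- list(
    format = "octflow-convmodel-1",
    kind = model@kind,
    config = model@config,
    manifest = model@manifest,
    trained = model@trained,
    params = lapply(model@params, function(p)
      list(W = list(dim = dim(p$W), data = as.numeric(p$W)),
           b = as.numeric(p$b)))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "octflow-convmodel-1"))
    stop("unrecognized model file format")
  params <- lapply(x$params, function(p)
    list(W = array(p$W$data, p$W$dim), b = as.numeric(p$b)))
  manifest <- x$manifest
  new("ConvModel", kind = x$kind, params = params,
      config = lapply(x$config, function(v) v), manifest = manifest,
      trained = isTRUE(x$trained))
}

#' Export a vessel graph as GraphML and CSV edge table
#'
#' @param graph a \linkS4class{VesselGraph}.
#' @param basePath path without extension; writes basePath.graphml and
#'   basePath_edges.csv.
#' @export
writeVesselGraph <- function(graph, basePath) {
  e <- graph@edges
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = graph@nodes)
  igraph::write_graph(g, paste0(basePath, ".graphml"), format = "graphml")
  utils::write.csv(e, paste0(basePath, "_edges.csv"), row.names = FALSE)
  invisible(basePath)
}
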