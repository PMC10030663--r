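#' Create acquisition parameters
#'
#' Defaults correspond to a 1310 nm, 200 nm bandwidth swept protocol with a
#' Doppler pair spacing of 2.3 ms, a repeated-B-scan spacing of 0.21 s and
#' 14 repeats per slow-axis position. The effective Doppler pair spacing is
#' a free parameter of the protocol, not derived from the A-scan rate.
#'
#' @param lambda0 centre wavelength, micrometres.
#' @param deltaLambda source bandwidth FWHM, micrometres.
#' @param nTissue tissue refractive index (typical cortex 1.35).
#' @param dtODT Doppler pair spacing, seconds.
#' @param dtOCA repeated-B-scan spacing, seconds.
#' @param nRepeats repeated frames per slow-axis position.
#' @param voxelPitch (z, x, y) micrometres per voxel.
#' @param axialPSF axial point-spread-function width, micrometres.
#' @return an \linkS4class{AcquisitionParams} object.
#' @examples
#' p <- acquisitionParams()
#' dopplerPhase(20, 0, p)  # expected phase for 20 um/s axial flow
#' @export
acquisitionParams <- function(lambda0 = 1.31, deltaLambda = 0.20,
                              nTissue = 1.35, dtODT = 2.3e-3, dtOCA = 0.21,
                              nRepeats = 14L,
                              voxelPitch = c(z = 3, x = 3, y = 3),
                              axialPSF = 2.5) {
  new("AcquisitionParams", lambda0 = lambda0, deltaLambda = deltaLambda,
      nTissue = nTissue, dtODT = dtODT, dtOCA = dtOCA,
      nRepeats = as.integer(nRepeats),
      voxelPitch = setNames(as.numeric(voxelPitch), c("z", "x", "y")),
      axialPSF = axialPSF)
}

#' Create a vessel tree from a segment table
#'
#' @param segments data.frame with columns id, parent, z0, x0, y0, z1, x1,
#'   y1, radius, speed, class.
#' @param flowSense +1 for arterial (root to leaves), -1 for venous.
#' @param domain bounding box (zmin, zmax, xmin, xmax, ymin, ymax), um.
#' @return a \linkS4class{VesselTree}.
#' @export
vesselTree <- function(segments, flowSense = 1,
                       domain = c(0, max(segments$z1), 0, max(segments$x1),
                                  0, max(segments$y1))) {
  new("VesselTree", segments = segments, flowSense = flowSense,
      domain = as.numeric(domain))
}

#' Create a bulk-motion trace
#'
#' @param deltaZ matrix (nRepeats x nY) of axial displacements, um.
#' @param scramble logical matrix of severe-corruption flags (defaults to
#'   all-FALSE).
#' @param scrambleAmplitude phase-scramble mixing amplitude in [0, 1].
#' @return a \linkS4class{MotionTrace}.
#' @export
motionTrace <- function(deltaZ, scramble = NULL, scrambleAmplitude = 1) {
  if (is.null(scramble))
    scramble <- matrix(FALSE, nrow(deltaZ), ncol(deltaZ))
  new("MotionTrace", deltaZ = deltaZ, scramble = scramble,
      scrambleAmplitude = scrambleAmplitude)
}

#' Create a reconstruction configuration
#'
#' @param nSelect target number of selected correlated frames.
#' @param rThreshold Pearson correlation threshold for frame selection.
#' @param phaseWindow (z, x) complex averaging window for phase subtraction.
#' @return a \linkS4class{ReconConfig}.
#' @export
reconConfig <- function(nSelect = 6L, rThreshold = 0.9,
                        phaseWindow = c(3L, 3L)) {
  new("ReconConfig", nSelect = as.integer(nSelect), rThreshold = rThreshold,
      phaseWindow = as.integer(phaseWindow))
}

#' Create an augmentation specification
#'
#' @param nControl interior control points of the monotone intensity remap.
#' @param cropFraction fraction of vessel segments dropped by vessel
#'   cropping.
#' @param segmentLength dropped-segment radius range, voxels.
#' @param noiseSD additive input perturbation (fraction of normalized
#'   range).
#' @param seed augmentation seed.
#' @return an \linkS4class{AugmentationSpec}.
#' @export
augmentationSpec <- function(nControl = 4L, cropFraction = 0.3,
                             segmentLength = c(3, 6), noiseSD = 0.05,
                             seed = 1L) {
  new("AugmentationSpec", nControl = as.integer(nControl),
      cropFraction = cropFraction, segmentLength = as.numeric(segmentLength),
      noiseSD = noiseSD, seed = as.integer(seed))
}

#' Create a stripe mask
#'
#' @param bands integer matrix with columns start, end (0-based half-open).
#' @param scores per-band detection score.
#' @param nSlow slow-axis extent.
#' @return a \linkS4class{StripeMask}.
#' @export
stripeMask <- function(bands = matrix(integer(0), 0, 2,
                                      dimnames = list(NULL, c("start", "end"))),
                       scores = numeric(nrow(bands)), nSlow) {
  storage.mode(bands) <- "integer"
  colnames(bands) <- c("start", "end")
  new("StripeMask", bands = bands, scores = scores,
      nSlow = as.integer(nSlow))
}

#' Create a vesselness mask
#'
#' @param mask logical array.
#' @param inpainted logical array marking model-predicted pixels.
#' @return a \linkS4class{VesselnessMask}.
#' @export
vesselnessMask <- function(mask, inpainted = array(FALSE, dim(mask))) {
  storage.mode(mask) <- "logical"
  storage.mode(inpainted) <- "logical"
  new("VesselnessMask", mask = mask, inpainted = inpainted)
}

## ---- accessors ------------------------------------------------------------

#' Number of repeated frames of a protocol or acquisition
#' @param object an \linkS4class{AcquisitionParams} or
#'   \linkS4class{ComplexAcquisition}.
#' @export
nRepeats <- function(object) {
  if (is(object, "AcquisitionParams")) object@nRepeats else object@params@nRepeats
}

#' Acquired complex field
#' @param acq a \linkS4class{ComplexAcquisition}.
#' @return the complex (z, x, r, y) array.
#' @export
acqField <- function(acq) acq@field

#' Ground-truth sidecar of an acquisition
#' @param acq a \linkS4class{ComplexAcquisition}.
#' @return the truth list.
#' @export
acqTruth <- function(acq) acq@truth

#' Acquisition parameters of an object
#' @param object a \linkS4class{ComplexAcquisition} or
#'   \linkS4class{ODTVolume}.
#' @return an \linkS4class{AcquisitionParams}.
#' @export
acqParams <- function(object) object@params

#' Volume data accessors
#'
#' \code{volData} returns the numeric array of an \code{ODTVolume},
#' \code{OCAVolume}, \code{OrientationField} (theta_z) or
#' \code{VesselnessMask} (logical mask).
#' @param object the container.
#' @return a numeric or logical array.
#' @export
volData <- function(object) {
  if (is(object, "ODTVolume") || is(object, "OCAVolume")) return(object@data)
  if (is(object, "OrientationField")) return(object@thetaZ)
  if (is(object, "VesselnessMask")) return(object@mask)
  stop("no data accessor for class ", class(object))
}

#' @rdname volData
#' @export
maskArray <- function(object) object@mask

#' @rdname volData
#' @export
inpaintedArray <- function(object) object@inpainted

#' Units of a Doppler volume ("rad" or "um/s")
#' @param object an \linkS4class{ODTVolume}.
#' @export
volUnits <- function(object) object@units

#' Stripe bands of a StripeMask (0-based, half-open)
#' @param object a \linkS4class{StripeMask}.
#' @export
stripeBands <- function(object) object@bands

#' Frames used per slow-axis position by the angiography reconstruction
#' @param object an \linkS4class{OCAVolume}.
#' @export
framesUsed <- function(object) object@framesUsed

#' Segment table of a vessel tree
#' @param tree a \linkS4class{VesselTree}.
#' @export
treeSegments <- function(tree) tree@segments

#' Edge/node tables of a vessel graph
#' @param graph a \linkS4class{VesselGraph}.
#' @export
graphEdges <- function(graph) graph@edges

#' @rdname graphEdges
#' @export
graphNodes <- function(graph) graph@nodes

#' Per-ROI series and compartment means of a flow time series
#' @param object a \linkS4class{FlowTimeSeries}.
#' @export
tsSeries <- function(object) object@series

#' @rdname tsSeries
#' @export
tsCompartments <- function(object) object@compartments

#' Training manifest of a convolutional model
#' @param model a \linkS4class{ConvModel}.
#' @export
modelManifest <- function(model) model@manifest

## ---- show methods ---------------------------------------------------------

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams: lambda0", object@lambda0 * 1e3, "nm,",
      "dtODT", object@dtODT * 1e3, "ms, dtOCA", object@dtOCA, "s,",
      object@nRepeats, "repeats, pitch",
      paste(object@voxelPitch, collapse = "x"), "um\n")
})

setMethod("show", "VesselTree", function(object) {
  s <- object@segments
  cat("VesselTree:", nrow(s), "segments (",
      paste(sprintf("%s=%d", names(table(s$class)), table(s$class)),
            collapse = ", "),
      "), flow sense", ifelse(object@flowSense > 0, "root->leaves",
                              "leaves->root"), "\n")
})

setMethod("show", "ComplexAcquisition", function(object) {
  d <- dim(object@field)
  cat("ComplexAcquisition:", paste(d, collapse = " x "),
      "(z, x, r, y);", sum(object@truth$corrupted), "corrupted frames\n")
})

setMethod("show", "ODTVolume", function(object) {
  cat("ODTVolume:", paste(dim(object@data), collapse = " x "),
      "(z, x, y) in", object@units,
      if (object@angleCorrected) "(angle corrected)" else
        "(not angle corrected)", "\n")
})

setMethod("show", "OCAVolume", function(object) {
  cat("OCAVolume:", paste(dim(object@data), collapse = " x "),
      "(z, x, y); speckle variance in [",
      signif(min(object@data), 3), ",", signif(max(object@data), 3), "]\n")
})

setMethod("show", "StripeMask", function(object) {
  cat("StripeMask:", nrow(object@bands), "band(s) on", object@nSlow,
      "slow-axis positions\n")
})

setMethod("show", "VesselnessMask", function(object) {
  cat("VesselnessMask:", paste(dim(object@mask), collapse = " x "), "-",
      sum(object@mask), "foreground,", sum(object@inpainted),
      "inpainted\n")
})

setMethod("show", "ConvModel", function(object) {
  cat("ConvModel <", object@kind, ">",
      if (object@trained) sprintf("trained (loss %.4g -> %.4g)",
                                  object@manifest$initLoss,
                                  object@manifest$finalLoss)
      else "untrained", "\n")
})

setMethod("show", "VesselGraph", function(object) {
  cat("VesselGraph:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges (",
      paste(sprintf("%s=%d", names(table(object@edges$compartment)),
                    table(object@edges$compartment)), collapse = ", "),
      ")\n")
})

setMethod("show", "FlowTimeSeries", function(object) {
  cat("FlowTimeSeries:", length(unique(object@series$roi)), "ROI(s),",
      length(unique(object@series$t)), "time points; baseline",
      length(object@baseline), "points\n")
})
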