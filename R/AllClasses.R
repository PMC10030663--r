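## Central S4 containers. Arrays follow the package grid convention:
## volumes are indexed (z, x, y) with z the beam/depth axis, acquisitions
## (z, x, r, y) with r the repeated-B-scan axis. Physical coordinates are in
## micrometres from the volume origin; ROIs and bands are 0-based, half-open.

#' Acquisition parameters shared by the phantom and the reconstruction
#'
#' Optical and timing constants of the scan protocol: centre wavelength and
#' source bandwidth, tissue refractive index, the time between the two
#' A-scans differenced for Doppler flow (\code{dtODT}), the time between
#' adjacent repeated B-scans used for angiography (\code{dtOCA}), the number
#' of repeated B-scan frames per slow-axis position, and the voxel pitch.
#'
#' @slot lambda0 centre wavelength, micrometres.
#' @slot deltaLambda source bandwidth (FWHM), micrometres.
#' @slot nTissue tissue refractive index, dimensionless.
#' @slot dtODT time between the two A-scans of a Doppler pair, seconds.
#' @slot dtOCA time between adjacent repeated B-scans, seconds.
#' @slot nRepeats repeated B-scan frames per slow-axis position.
#' @slot voxelPitch named numeric (z, x, y), micrometres per voxel.
#' @slot axialPSF axial point-spread-function width, micrometres (direct
#'   parameter; no spectrometer model is implied).
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    lambda0 = "numeric", deltaLambda = "numeric", nTissue = "numeric",
    dtODT = "numeric", dtOCA = "numeric", nRepeats = "integer",
    voxelPitch = "numeric", axialPSF = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  v <- c(object@lambda0, object@deltaLambda, object@nTissue, object@dtODT,
         object@dtOCA, object@voxelPitch, object@axialPSF)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all optical/timing parameters must be strictly positive")
  if (object@nRepeats < 2L) return("nRepeats must be >= 2")
  if (object@dtOCA <= object@dtODT) return("dtOCA must exceed dtODT")
  if (length(object@voxelPitch) != 3L)
    return("voxelPitch must have length 3 (z, x, y)")
  TRUE
})

#' Synthetic vascular tree
#'
#' Segments are straight tubes joined at bifurcations; flow is conserved at
#' every bifurcation by construction (children split the parent volumetric
#' flow, radii follow a cube-root law). \code{flowSense} is +1 when flow runs
#' root-to-leaves (arterial trees) and -1 leaves-to-root (venous trees).
#'
#' @slot segments data.frame with columns id, parent (NA at root), z0, x0,
#'   y0, z1, x1, y1 (micrometres), radius (micrometres), speed (mean lumen
#'   speed, micrometres/second), class (arteriole/venule/capillary).
#' @slot flowSense +1 (root to leaves) or -1 (leaves to root).
#' @slot domain numeric length-6 bounding box (zmin, zmax, xmin, xmax, ymin,
#'   ymax), micrometres.
#' @exportClass VesselTree
setClass("VesselTree",
  representation(segments = "data.frame", flowSense = "numeric",
                 domain = "numeric")
)

setValidity("VesselTree", function(object) {
  s <- object@segments
  need <- c("id", "parent", "z0", "x0", "y0", "z1", "x1", "y1", "radius",
            "speed", "class")
  if (!all(need %in% names(s))) return("segments is missing columns")
  if (any(s$radius <= 0)) return("radii must be > 0")
  if (!object@flowSense %in% c(-1, 1)) return("flowSense must be +1 or -1")
  ## acyclic + child radius <= parent + flow conservation (5%)
  idx <- match(s$parent, s$id)
  if (any(!is.na(idx) & idx == seq_len(nrow(s))))
    return("segment cannot be its own parent")
  for (i in seq_len(nrow(s))) {
    seen <- integer(0); j <- i
    while (!is.na(s$parent[j])) {
      j <- match(s$parent[j], s$id)
      if (is.na(j)) return("parent id not found")
      if (j %in% seen) return("tree contains a cycle")
      seen <- c(seen, j)
    }
  }
  ok <- is.na(idx) | s$radius <= s$radius[idx] + 1e-9
  if (!all(ok)) return("child radius must not exceed parent radius")
  flow <- pi * s$radius^2 * s$speed
  for (p in s$id[s$id %in% s$parent]) {
    kids <- which(!is.na(s$parent) & s$parent == p)
    fp <- flow[match(p, s$id)]
    if (abs(sum(flow[kids]) - fp) > 0.05 * fp)
      return("flow not conserved at a bifurcation (tolerance 5%)")
  }
  TRUE
})

#' Bulk-motion trace
#'
#' Per-frame axial displacement and corruption flags. Flagged frames are
#' phase-scrambled with mixing amplitude \code{scrambleAmplitude} (1 = full
#' scramble) so that they decorrelate from their neighbours.
#'
#' @slot deltaZ matrix (nRepeats x nY) of axial displacements, micrometres.
#' @slot scramble logical matrix (nRepeats x nY) of severe-corruption flags.
#' @slot scrambleAmplitude mixing amplitude in [0, 1].
#' @exportClass MotionTrace
setClass("MotionTrace",
  representation(deltaZ = "matrix", scramble = "matrix",
                 scrambleAmplitude = "numeric")
)

setValidity("MotionTrace", function(object) {
  if (!all(dim(object@deltaZ) == dim(object@scramble)))
    return("deltaZ and scramble must have identical dimensions")
  if (object@scrambleAmplitude < 0 || object@scrambleAmplitude > 1)
    return("scrambleAmplitude must lie in [0, 1]")
  TRUE
})

#' Complex OCT acquisition with ground-truth sidecar
#'
#' The raw data model: a complex voxel field indexed (z, x, r, y) where the
#' A-scan at fast-axis index x of repeat frame r is acquired at time
#' r*dtOCA + x*dtODT. The ground-truth sidecar carries the rasterized vessel
#' labels, speeds, axial velocities, Doppler angles, the forward-model phase
#' difference (wrapped), aliasing flags and the injected corrupted-frame set.
#'
#' @slot field complex array (z, x, r, y).
#' @slot params an \code{AcquisitionParams}.
#' @slot truth list: label, speed, vz, thetaZ, dphi, aliased arrays on the
#'   (z, x, y) grid, plus corrupted (logical nRepeats x nY matrix).
#' @exportClass ComplexAcquisition
setClass("ComplexAcquisition",
  representation(field = "array", params = "AcquisitionParams",
                 truth = "list")
)

setValidity("ComplexAcquisition", function(object) {
  d <- dim(object@field)
  if (length(d) != 4L) return("field must be a 4D (z, x, r, y) array")
  if (any(!is.finite(Re(object@field))) || any(!is.finite(Im(object@field))))
    return("field must be finite")
  tr <- object@truth
  grid <- d[c(1L, 2L, 4L)]
  for (nm in c("label", "speed", "vz", "thetaZ", "dphi", "aliased"))
    if (!is.null(tr[[nm]]) && !all(dim(tr[[nm]]) == grid))
      return(sprintf("truth$%s must share the (z, x, y) grid", nm))
  if (!is.null(tr$corrupted) && !all(dim(tr$corrupted) == d[c(3L, 4L)]))
    return("truth$corrupted must be (nRepeats x nY)")
  TRUE
})

#' Reconstructed Doppler (flow) volume
#'
#' Signed Doppler phase difference per voxel in (-pi, pi], optionally
#' converted to axial velocity (micrometres/second). Displayed/derived
#' quantities are not Doppler-angle corrected unless
#' \code{angleCorrected} is TRUE.
#'
#' @slot data numeric array (z, x, y).
#' @slot params an \code{AcquisitionParams}.
#' @slot units "rad" or "um/s".
#' @slot angleCorrected logical.
#' @slot lowConfidence logical array flagging zero-amplitude voxels.
#' @exportClass ODTVolume
setClass("ODTVolume",
  representation(data = "array", params = "AcquisitionParams",
                 units = "character", angleCorrected = "logical",
                 lowConfidence = "array")
)

setValidity("ODTVolume", function(object) {
  if (object@units == "rad") {
    v <- object@data[is.finite(object@data)]
    if (length(v) && (max(v) > pi + 1e-9 || min(v) <= -pi - 1e-9))
      return("phase data must lie in (-pi, pi]")
  }
  if (!object@units %in% c("rad", "um/s"))
    return("units must be 'rad' or 'um/s'")
  TRUE
})

#' Reconstructed angiography (speckle-variance) volume
#'
#' Per-voxel coefficient of variation (std/mean) of intensity across the
#' selected repeated B-scans.
#'
#' @slot data non-negative numeric array (z, x, y).
#' @slot framesUsed list (length nY) of selected repeat indices.
#' @slot selectionWarn logical vector (length nY): fewer than 2 frames met
#'   the correlation threshold at that position.
#' @exportClass OCAVolume
setClass("OCAVolume",
  representation(data = "array", framesUsed = "list",
                 selectionWarn = "logical")
)

setValidity("OCAVolume", function(object) {
  if (any(object@data < 0)) return("speckle-variance data must be >= 0")
  if (length(object@framesUsed) &&
      any(vapply(object@framesUsed, length, 1L) < 2L))
    return("at least 2 frames must be used at every slow-axis position")
  TRUE
})

#' Reconstruction configuration
#'
#' @slot nSelect target number of selected correlated frames (default 6).
#' @slot rThreshold Pearson correlation threshold (default 0.9).
#' @slot phaseWindow (z, x) averaging window for the complex lag-1 products
#'   before the argument is taken.
#' @exportClass ReconConfig
setClass("ReconConfig",
  representation(nSelect = "integer", rThreshold = "numeric",
                 phaseWindow = "integer")
)

setValidity("ReconConfig", function(object) {
  if (object@nSelect < 2L) return("nSelect must be >= 2")
  if (object@rThreshold <= 0 || object@rThreshold >= 1)
    return("rThreshold must lie in (0, 1)")
  if (length(object@phaseWindow) != 2L || any(object@phaseWindow < 1L))
    return("phaseWindow must be two positive integers (z, x)")
  TRUE
})

#' Stripe (bulk-motion artifact) mask
#'
#' Corrupted slow-axis bands of an en-face image, stored as 0-based,
#' half-open [start, end) index intervals with a detection score per band.
#'
#' @slot bands integer matrix with columns start, end (0-based, half-open).
#' @slot scores numeric robust z-score per band.
#' @slot nSlow slow-axis extent the bands index into.
#' @exportClass StripeMask
setClass("StripeMask",
  representation(bands = "matrix", scores = "numeric", nSlow = "integer")
)

setValidity("StripeMask", function(object) {
  b <- object@bands
  if (ncol(b) != 2L) return("bands must have columns start, end")
  if (nrow(b)) {
    if (any(b[, 1L] >= b[, 2L])) return("bands must be non-empty intervals")
    if (any(b[, 1L] < 0L) || any(b[, 2L] > object@nSlow))
      return("bands must lie within image bounds")
    o <- order(b[, 1L])
    if (nrow(b) > 1L && any(b[o, 2L][-nrow(b)] > b[o, 1L][-1L]))
      return("bands must be disjoint")
  }
  TRUE
})

#' Binary vesselness mask
#'
#' @slot mask logical array (2D en-face or 3D).
#' @slot inpainted logical array, same shape: TRUE where the value was
#'   predicted by the inpainting model rather than segmented.
#' @exportClass VesselnessMask
setClass("VesselnessMask",
  representation(mask = "array", inpainted = "array")
)

setValidity("VesselnessMask", function(object) {
  if (!is.logical(object@mask) || !is.logical(object@inpainted))
    return("mask and inpainted must be logical arrays")
  if (!all(dim(object@mask) == dim(object@inpainted)))
    return("mask and inpainted must have identical shape")
  TRUE
})

#' Trained convolutional model (inpainting or enhancement)
#'
#' Holds the learned parameters, the training configuration and a manifest
#' (per-iteration losses, seed, normalization) sufficient to reproduce the
#' run on one platform.
#'
#' @slot kind "inpaint2d" or "enhance3d".
#' @slot params nested list of weight arrays.
#' @slot config list of architecture/optimizer settings.
#' @slot manifest list: seed, losses, initLoss, finalLoss, normalization.
#' @slot trained logical.
#' @exportClass ConvModel
setClass("ConvModel",
  representation(kind = "character", params = "list", config = "list",
                 manifest = "list", trained = "logical")
)

#' Augmentation specification for self-supervised volume enhancement
#'
#' @slot nControl number of interior control points of the monotone
#'   piecewise-linear intensity remap (drawn from empirical vessel-intensity
#'   quantiles).
#' @slot cropFraction fraction f of vessel segments to drop (0 <= f < 1).
#' @slot segmentLength length-2 range of dropped-segment radii, voxels.
#' @slot noiseSD additive input-noise perturbation (fraction of the
#'   normalized intensity range) applied to inputs only.
#' @slot seed integer seed for all augmentation randomness.
#' @exportClass AugmentationSpec
setClass("AugmentationSpec",
  representation(nControl = "integer", cropFraction = "numeric",
                 segmentLength = "numeric", noiseSD = "numeric",
                 seed = "integer")
)

setValidity("AugmentationSpec", function(object) {
  if (object@cropFraction < 0 || object@cropFraction >= 1)
    return("cropFraction must lie in [0, 1)")
  if (length(object@segmentLength) != 2L || any(object@segmentLength <= 0))
    return("segmentLength must be a positive length-2 range")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

#' Per-voxel vessel orientation field
#'
#' Doppler angle theta_z (degrees in [0, 90], NA where undefined), vessel
#' axis unit vectors and a [0, 1] confidence from Hessian anisotropy.
#'
#' @slot thetaZ numeric array (z, x, y), degrees.
#' @slot axis numeric array (z, x, y, 3) of unit vectors (z, x, y order).
#' @slot confidence numeric array in [0, 1].
#' @exportClass OrientationField
setClass("OrientationField",
  representation(thetaZ = "array", axis = "array", confidence = "array")
)

setValidity("OrientationField", function(object) {
  th <- object@thetaZ[is.finite(object@thetaZ)]
  if (length(th) && (min(th) < -1e-6 || max(th) > 90 + 1e-6))
    return("thetaZ must lie in [0, 90] degrees")
  cf <- object@confidence[is.finite(object@confidence)]
  if (length(cf) && (min(cf) < 0 || max(cf) > 1 + 1e-9))
    return("confidence must lie in [0, 1]")
  TRUE
})

#' Vessel centerline graph
#'
#' Nodes are junctions/endpoints with physical positions; edges are
#' centerline chains carrying the mean signed Doppler value, mean diameter,
#' mean Doppler angle and a compartment label.
#'
#' @slot nodes data.frame: id, z, x, y (micrometres).
#' @slot edges data.frame: from, to, signedDoppler, diameter, thetaZ,
#'   compartment (arteriole/venule/capillary/unclassified), tree id and
#'   conflict score.
#' @exportClass VesselGraph
setClass("VesselGraph",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("VesselGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% object@nodes$id))
      return("edge endpoints must be nodes")
    if (any(e$diameter <= 0)) return("diameters must be > 0")
    if (any(!is.finite(e$signedDoppler)))
      return("signed Doppler values must be finite")
  }
  TRUE
})

#' Per-ROI flow time series
#'
#' CBFv(t) per region of interest with relative changes against a baseline
#' window; the baseline mean of the relative change is 0 by construction.
#'
#' @slot series data.frame: roi, compartment, t, cbfv, dcbfv.
#' @slot baseline integer indices of the baseline time points.
#' @slot compartments data.frame: compartment, t, mean dcbfv, sd.
#' @exportClass FlowTimeSeries
setClass("FlowTimeSeries",
  representation(series = "data.frame", baseline = "integer",
                 compartments = "data.frame")
)
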