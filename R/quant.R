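## Vascular network quantification: Hessian orientation tracking, Doppler
## angle correction, arteriole/venule discrimination from branching flow
## direction, diameters, skeleton capillary density and ROI flow dynamics.

#' Per-voxel vessel orientation from the scale-normalized Hessian
#'
#' At each scale the image is smoothed with a Gaussian and the
#' sigma^2-normalized Hessian is eigendecomposed per voxel; the vessel axis
#' is the eigenvector of the smallest-magnitude eigenvalue and theta_z is
#' the angle between that axis and the beam (z) direction. The per-voxel
#' scale is selected by maximal eigenvalue anisotropy; near-isotropic
#' voxels get confidence 0 and an undefined (NA) angle.
#'
#' @param volume 3D array or \linkS4class{ODTVolume} (phase magnitude).
#' @param scales Gaussian sigmas, voxels (default c(1, 2, 4)).
#' @param confFloor anisotropy below which the angle is flagged undefined.
#' @return an \linkS4class{OrientationField}.
#' @export
hessianOrientation <- function(volume, scales = c(1, 2, 4),
                               confFloor = 0.05) {
  if (any(scales <= 0)) stop("scales must be positive")
  v <- if (is(volume, "ODTVolume")) abs(volume@data) else as.array(volume)
  d <- dim(v)
  best <- list(conf = array(-Inf, d))
  for (sg in scales) {
    g0 <- gaussKernel(sg, 0L)
    g1 <- gaussKernel(sg, 1L)
    g2 <- gaussKernel(sg, 2L)
    dz <- function(v, kz, kx, ky) {
      a <- .convAxis(array(v, d), d, kz, 0L)
      a <- .convAxis(a, d, kx, 1L)
      .convAxis(a, d, ky, 2L)
    }
    s2 <- sg^2
    hzz <- s2 * dz(v, g2, g0, g0)
    hxx <- s2 * dz(v, g0, g2, g0)
    hyy <- s2 * dz(v, g0, g0, g2)
    hzx <- s2 * dz(v, g1, g1, g0)
    hzy <- s2 * dz(v, g1, g0, g1)
    hxy <- s2 * dz(v, g0, g1, g1)
    ev <- .sym3Eigen(hzz, hxx, hyy, hzx, hzy, hxy)
    an <- (abs(ev$l3) - abs(ev$l1)) / (abs(ev$l3) + abs(ev$l1) + 1e-12)
    tol <- 1e-10 * max(abs(v)) + 1e-300   # flat regions: no structure
    bright <- ev$l2 < 0 & ev$l3 < 0 & abs(ev$l3) > tol
    conf <- ifelse(bright, an, 0)
    upd <- conf > best$conf
    if (identical(sg, scales[1])) upd <- rep(TRUE, length(conf))
    for (nm in c("v1", "v2", "v3")) {
      if (is.null(best[[nm]])) best[[nm]] <- array(0, d)
      best[[nm]][upd] <- ev[[nm]][upd]
    }
    best$conf[upd] <- conf[upd]
  }
  conf <- array(pmin(pmax(best$conf, 0), 1), d)
  theta <- array(acos(pmin(1, abs(best$v1))) * 180 / pi, d)
  theta[conf < confFloor] <- NA_real_
  ax <- array(c(best$v1, best$v2, best$v3), c(d, 3L))
  new("OrientationField", thetaZ = theta, axis = ax, confidence = conf)
}

#' Doppler-angle-corrected velocity
#'
#' Converts a phase-unit Doppler volume to axial-geometry-corrected speed:
#' v = lambda0 * dphi / (4 pi n dtODT cos(theta_z)). The correction factor
#' 1/cos(theta_z) diverges for near-horizontal flows, so voxels with
#' theta_z above \code{thetaMax} (or undefined) are masked NA rather than
#' amplified.
#'
#' @param odt an \linkS4class{ODTVolume} in phase units.
#' @param orient an \linkS4class{OrientationField} on the same grid.
#' @param thetaMax maximal correctable Doppler angle, degrees (default 80).
#' @return an \linkS4class{ODTVolume} in um/s with angleCorrected = TRUE.
#' @export
angleCorrectVelocity <- function(odt, orient, thetaMax = 80) {
  if (!is(odt, "ODTVolume") || odt@units != "rad")
    stop("odt must be an ODTVolume in phase units with params attached")
  p <- odt@params
  th <- orient@thetaZ
  if (!all(dim(th) == dim(odt@data))) stop("orientation grid mismatch")
  cosz <- cos(th * pi / 180)
  vel <- p@lambda0 * odt@data / (4 * pi * p@nTissue * p@dtODT * cosz)
  vel[is.na(th) | th > thetaMax] <- NA_real_
  new("ODTVolume", data = vel, params = p, units = "um/s",
      angleCorrected = TRUE, lowConfidence = odt@lowConfidence)
}

#' Build a vessel graph from a phantom tree
#'
#' Nodes are segment junctions and endpoints; each tree segment becomes an
#' edge carrying its diameter, Doppler angle and mean signed Doppler value,
#' sampled along the rasterized centerline of a reconstructed Doppler
#' volume when one is given, otherwise taken from the forward model.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param params an \linkS4class{AcquisitionParams}.
#' @param odt optional \linkS4class{ODTVolume} to sample Doppler values
#'   from.
#' @return a \linkS4class{VesselGraph} (compartments unclassified).
#' @export
buildVesselGraph <- function(tree, params, odt = NULL) {
  s <- tree@segments
  nodeId <- function(i) {
    if (is.na(s$parent[i])) paste0("s", s$id[i]) else paste0("e", s$parent[i])
  }
  nodes <- rbind(
    do.call(rbind, lapply(which(is.na(s$parent)), function(i)
      data.frame(id = paste0("s", s$id[i]), z = s$z0[i], x = s$x0[i],
                 y = s$y0[i]))),
    do.call(rbind, lapply(seq_len(nrow(s)), function(i)
      data.frame(id = paste0("e", s$id[i]), z = s$z1[i], x = s$x1[i],
                 y = s$y1[i])))
  )
  nodes <- nodes[!duplicated(nodes$id), ]
  dom <- tree@domain
  pitch <- params@voxelPitch
  sampleODT <- function(i) {
    p0 <- c(s$z0[i], s$x0[i], s$y0[i]); p1 <- c(s$z1[i], s$x1[i], s$y1[i])
    len <- sqrt(sum((p1 - p0)^2))
    tpts <- seq(0, 1, length.out = max(3L, ceiling(len / min(pitch))))
    pts <- t(sapply(tpts, function(t) p0 + t * (p1 - p0)))
    idx <- cbind(pmin(pmax(floor((pts[, 1] - dom[1]) / pitch[1]) + 1L, 1L),
                      dim(odt@data)[1]),
                 pmin(pmax(floor((pts[, 2] - dom[3]) / pitch[2]) + 1L, 1L),
                      dim(odt@data)[2]),
                 pmin(pmax(floor((pts[, 3] - dom[5]) / pitch[3]) + 1L, 1L),
                      dim(odt@data)[3]))
    mean(odt@data[idx])
  }
  edges <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    u <- c(s$z1[i] - s$z0[i], s$x1[i] - s$x0[i], s$y1[i] - s$y0[i])
    u <- u / sqrt(sum(u^2))
    vz <- tree@flowSense * s$speed[i] * u[1]
    sd0 <- if (is.null(odt)) {
      4 * pi * params@nTissue * vz * params@dtODT / params@lambda0
    } else sampleODT(i)
    data.frame(from = nodeId(i), to = paste0("e", s$id[i]),
               signedDoppler = sd0, diameter = 2 * s$radius[i],
               thetaZ = acos(min(1, abs(u[1]))) * 180 / pi,
               compartment = "unclassified", tree = NA_integer_,
               conflict = NA_real_)
  }))
  new("VesselGraph", nodes = nodes, edges = edges)
}

#' Classify arterioles and venules from branching flow direction
#'
#' The signed Doppler value of an edge, combined with the sign of the
#' edge's axial (z) direction, determines the flow sense along the edge. At
#' every bifurcation the tree votes: one inflow splitting into several
#' outflows means the tree branches out along the flow (arteriole); several
#' inflows merging into one outflow means it branches in (venule). Trees
#' whose largest diameter is at or below \code{capillaryCutoff} are
#' capillaries; trees with conflicting votes stay unclassified with a
#' conflict score; trees without bifurcations stay unclassified.
#'
#' @param graph a \linkS4class{VesselGraph}.
#' @param capillaryCutoff large-vessel diameter cutoff, um (default 10).
#' @param horizTol |z-component| of the edge direction below which the flow
#'   sense is ambiguous and the edge abstains.
#' @return the graph with compartment, tree and conflict columns filled.
#' @export
classifyArterioleVenule <- function(graph, capillaryCutoff = 10,
                                    horizTol = 0.05) {
  e <- graph@edges
  n <- graph@nodes
  if (!nrow(e)) return(graph)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = n$id)
  memb <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  e$tree <- unname(memb[e$from])
  pos <- function(id) unlist(n[match(id, n$id), c("z", "x", "y")])
  ## flow sense per edge: +1 = from -> to, -1 = to -> from, 0 = abstain
  sense <- vapply(seq_len(nrow(e)), function(i) {
    d <- pos(e$to[i]) - pos(e$from[i])
    d <- d / sqrt(sum(d^2))
    s <- sign(e$signedDoppler[i])
    if (abs(d[1]) < horizTol || s == 0) return(0)
    if (sign(d[1]) == s) 1 else -1
  }, 1)
  votes <- data.frame(tree = integer(0), vote = integer(0))
  for (v in n$id[deg[n$id] >= 3]) {
    inc <- which(e$from == v | e$to == v)
    io <- vapply(inc, function(i) {
      if (sense[i] == 0) return(0)
      if (e$to[i] == v) sense[i] else -sense[i]  # +1 = flows into v
    }, 1)
    io <- io[io != 0]
    if (length(io) < 3) next
    nin <- sum(io > 0); nout <- sum(io < 0)
    vote <- if (nin == 1 && nout >= 2) 1L          # branching out: arterial
            else if (nout == 1 && nin >= 2) -1L    # branching in: venous
            else 0L
    if (vote != 0L)
      votes <- rbind(votes, data.frame(tree = unname(memb[v]), vote = vote))
  }
  for (tr in unique(e$tree)) {
    sel <- e$tree == tr
    if (max(e$diameter[sel]) <= capillaryCutoff) {
      e$compartment[sel] <- "capillary"
      next
    }
    vv <- votes$vote[votes$tree == tr]
    if (!length(vv)) {
      e$compartment[sel] <- "unclassified"
    } else if (all(vv == 1L)) {
      e$compartment[sel] <- "arteriole"
      e$conflict[sel] <- 0
    } else if (all(vv == -1L)) {
      e$compartment[sel] <- "venule"
      e$conflict[sel] <- 0
    } else {
      e$compartment[sel] <- "unclassified"
      e$conflict[sel] <- min(mean(vv == 1L), mean(vv == -1L))
    }
  }
  graph@edges <- e
  graph
}

#' Capillary density from the skeletonized mask
#'
#' Large vessels (local diameter above the cutoff) are removed, the
#' remaining mask is skeletonized by morphological thinning, and the
#' capillary density is the skeleton length per ROI area (the fill factor -
#' foreground fraction - is reported alongside).
#'
#' @param mask en-face \linkS4class{VesselnessMask} or logical matrix
#'   (x, y).
#' @param largeVesselCutoff large-vessel diameter cutoff, um.
#' @param roi list(x = c(a, b), y = c(c, d)): 0-based half-open voxel box
#'   (NULL = whole image).
#' @param pitch (x, y) um per pixel.
#' @return list: cd (um/um^2), skeletonLength (um), roiArea (um^2),
#'   fillFactor, skeleton (logical matrix).
#' @export
skeletonCapillaryDensity <- function(mask, largeVesselCutoff = 10,
                                     roi = NULL, pitch = c(1, 1)) {
  m <- if (is(mask, "VesselnessMask")) maskArray(mask) else mask
  pitch <- unname(pitch)
  d <- dim(m)
  if (is.null(roi)) roi <- list(x = c(0, d[1]), y = c(0, d[2]))
  xi <- halfOpenToIdx(roi$x, d[1])
  yi <- halfOpenToIdx(roi$y, d[2])
  dt <- distTransform(m, spacing = pitch)
  core <- 2 * dt > largeVesselCutoff
  cap <- m
  if (any(core)) {
    toCore <- distTransform(!core, spacing = pitch)
    cap <- m & !(toCore <= largeVesselCutoff)
  }
  skel <- skeletonize2d(cap)
  skelRoi <- skel[xi, yi, drop = FALSE]
  len <- skeletonLength2d(skelRoi, pitch)
  area <- length(xi) * length(yi) * pitch[1] * pitch[2]
  list(cd = len / area, skeletonLength = len, roiArea = area,
       fillFactor = sum(m[xi, yi]) / (length(xi) * length(yi)),
       skeleton = skel)
}

#' Vessel diameter at centerline points
#'
#' Twice the Euclidean distance-transform value at each queried centerline
#' point, averaged along the segment. Points off the mask are an error.
#'
#' @param mask \linkS4class{VesselnessMask} or logical array (2D or 3D).
#' @param points integer matrix of 0-based voxel coordinates (one row per
#'   point, columns in grid order).
#' @param pitch um per voxel along each axis.
#' @return list: diameters (per point, um), mean.
#' @export
vesselDiameter <- function(mask, points, pitch = rep(1, ncol(points))) {
  m <- if (is(mask, "VesselnessMask")) maskArray(mask) else mask
  d <- dim(m)
  idx <- as.matrix(points) + 1L
  if (any(idx < 1L) || any(sweep(idx, 2, d, ">") != 0))
    stop("point outside the mask extent")
  if (!all(m[idx])) stop("point off the vessel mask")
  dt <- distTransform(m, spacing = pitch)
  dia <- 2 * dt[idx]
  list(diameters = dia, mean = mean(dia))
}

#' Per-ROI flow time series and relative changes
#'
#' For each ROI and time point the flow index CBFv is the mean Doppler
#' magnitude over ROI voxels above a noise floor; the relative change
#' dCBFv(t) = (CBFv - CBFv0)/CBFv0 uses the mean over the baseline window,
#' so the baseline mean of dCBFv is 0 by construction. Compartment traces
#' are the arithmetic mean (with sd) over member ROIs.
#'
#' @param volumes list of \linkS4class{ODTVolume}s (or arrays), one per
#'   time point, on a common grid.
#' @param rois list of list(name, box = list(z=, x=, y=), compartment);
#'   boxes are 0-based half-open voxel intervals.
#' @param baseline integer indices of the baseline time points (must
#'   precede the rest).
#' @param noiseFloor Doppler magnitude floor.
#' @return a \linkS4class{FlowTimeSeries}.
#' @export
roiFlowTimeseries <- function(volumes, rois, baseline, noiseFloor = 0.05) {
  if (length(volumes) < 2L) stop("need at least 2 time points")
  if (!length(baseline)) stop("baseline window must be non-empty")
  arrs <- lapply(volumes, function(v)
    if (is(v, "ODTVolume")) abs(v@data) else abs(v))
  d <- dim(arrs[[1]])
  rows <- list()
  for (ro in rois) {
    zi <- halfOpenToIdx(ro$box$z, d[1])
    xi <- halfOpenToIdx(ro$box$x, d[2])
    yi <- halfOpenToIdx(ro$box$y, d[3])
    cb <- vapply(arrs, function(a) {
      vals <- a[zi, xi, yi]
      vals <- vals[vals > noiseFloor]
      if (length(vals)) mean(vals) else 0
    }, 1)
    b0 <- mean(cb[baseline])
    rows[[length(rows) + 1L]] <-
      data.frame(roi = ro$name, compartment = ro$compartment,
                 t = seq_along(cb), cbfv = cb,
                 dcbfv = if (b0 > 0) (cb - b0) / b0 else NA_real_)
  }
  ser <- do.call(rbind, rows)
  comp <- do.call(rbind, lapply(split(ser, list(ser$compartment, ser$t),
                                      drop = TRUE), function(g)
    data.frame(compartment = g$compartment[1], t = g$t[1],
               mean = mean(g$dcbfv), sd = sd(g$dcbfv))))
  rownames(comp) <- NULL
  comp <- comp[order(comp$compartment, comp$t), ]
  new("FlowTimeSeries", series = ser, baseline = as.integer(baseline),
      compartments = comp)
}
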