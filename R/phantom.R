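## Phantom generator: synthetic vascular trees, complex OCT acquisitions and
## bulk-motion corruption, with ground-truth sidecars.

#' Evaluate code under a temporary RNG state
#'
#' Seeds the generator, evaluates the expression, and restores the caller's
#' RNG stream, so seeded generators never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

rotatedChildren <- function(dir, beta) {
  ## two unit vectors at +/- beta from dir, random azimuth
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  w <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  phi <- runif(1, 0, 2 * pi)
  uu <- cos(phi) * u + sin(phi) * w
  b <- beta * pi / 180
  d1 <- cos(b) * dir + sin(b) * uu
  d2 <- cos(b) * dir - sin(b) * uu
  list(d1 / sqrt(sum(d1^2)), d2 / sqrt(sum(d2^2)))
}

#' Generate a synthetic vascular tree
#'
#' Builds a binary branching tree that emulates a penetrating cortical
#' vessel: the root dives from the surface, each bifurcation splits the
#' parent volumetric flow between two children (cube-root radius law, so
#' flow is conserved exactly), and segment lengths shrink geometrically.
#' Segments whose diameter falls at or below
#' \code{compartmentSpec$capillaryMaxDiameter} are labelled capillaries,
#' the rest arterioles or venules according to \code{flowSense}.
#'
#' @param seed integer seed; identical seeds give identical trees.
#' @param depth number of bifurcation levels (0 = single root segment).
#' @param domain bounding box (zmin, zmax, xmin, xmax, ymin, ymax), um.
#' @param compartmentSpec list of generator knobs: rootRadius (um),
#'   rootSpeed (um/s), rootLength (um), lengthRatio, branchAngle (deg),
#'   polarAngle (deg, root tilt from the beam axis), flowSense (+1/-1),
#'   capillaryMaxDiameter (um), divingDepthRange (um, optional: rescale the
#'   tree so its deepest centerline point falls in this range).
#' @return a \linkS4class{VesselTree}.
#' @examples
#' tr <- generateVesselTree(1, depth = 2, domain = c(0, 190, 0, 190, 0, 190))
#' treeSegments(tr)[, c("id", "parent", "radius", "speed", "class")]
#' @export
generateVesselTree <- function(seed, depth,
                               domain = c(0, 192, 0, 192, 0, 192),
                               compartmentSpec = list()) {
  if (depth < 0) stop("depth must be >= 0")
  if (any(domain[c(2, 4, 6)] <= domain[c(1, 3, 5)]))
    stop("domain must be a non-empty box")
  cs <- modifyList(list(rootRadius = 10, rootSpeed = 80, rootLength = 55,
                        lengthRatio = 0.78, branchAngle = 32,
                        polarAngle = 28, flowSense = 1,
                        capillaryMaxDiameter = 10,
                        divingDepthRange = NULL), compartmentSpec)
  withSeed(seed, {
    segs <- list()
    nid <- 0L
    build <- function(start, dir, radius, speed, level, parent) {
      nid <<- nid + 1L
      id <- nid
      len <- cs$rootLength * cs$lengthRatio^level
      end <- start + dir * len
      segs[[id]] <<- data.frame(id = id, parent = parent,
                                z0 = start[1], x0 = start[2], y0 = start[3],
                                z1 = end[1], x1 = end[2], y1 = end[3],
                                radius = radius, speed = speed)
      if (level < depth) {
        w <- runif(1, 0.4, 0.6)
        ch <- rotatedChildren(dir, cs$branchAngle)
        for (k in 1:2) {
          wk <- if (k == 1) w else 1 - w
          build(end, ch[[k]], radius * wk^(1 / 3), speed * wk^(1 / 3),
                level + 1L, id)
        }
      }
    }
    a <- cs$polarAngle * pi / 180
    az <- runif(1, 0, 2 * pi)
    dir0 <- c(cos(a), sin(a) * cos(az), sin(a) * sin(az))
    start0 <- c(domain[1] + 0.02 * (domain[2] - domain[1]),
                (domain[3] + domain[4]) / 2, (domain[5] + domain[6]) / 2)
    build(start0, dir0, cs$rootRadius, cs$rootSpeed, 0L, NA_integer_)
    s <- do.call(rbind, segs)
    if (!is.null(cs$divingDepthRange)) {
      target <- runif(1, cs$divingDepthRange[1], cs$divingDepthRange[2])
      deepest <- max(s$z0, s$z1)
      f <- target / deepest
      s$z0 <- s$z0 * f
      s$z1 <- s$z1 * f
    }
    ## keep centerlines inside the domain (clip endpoints)
    s$z1 <- pmin(pmax(s$z1, domain[1]), domain[2])
    s$x1 <- pmin(pmax(s$x1, domain[3]), domain[4])
    s$y1 <- pmin(pmax(s$y1, domain[5]), domain[6])
    s$class <- ifelse(2 * s$radius <= cs$capillaryMaxDiameter, "capillary",
                      ifelse(cs$flowSense > 0, "arteriole", "venule"))
    vesselTree(s, flowSense = cs$flowSense, domain = domain)
  })
}

#' Generate a bed of independent capillary segments
#'
#' Capillaries are rendered as near single-voxel-radius tubes with speeds in
#' the stated range. With \code{inPlane = TRUE} the segments lie in constant-z
#' planes so that their en-face projected length equals their true length
#' (useful for density ground truth).
#'
#' @param seed integer seed.
#' @param n number of capillary segments.
#' @param domain bounding box, um.
#' @param speedRange speed range, um/s.
#' @param radius capillary radius, um.
#' @param lengthRange segment length range, um.
#' @param inPlane constrain segments to constant depth.
#' @return a \linkS4class{VesselTree} of unconnected capillary segments.
#' @export
generateCapillaryBed <- function(seed, n = 24,
                                 domain = c(0, 192, 0, 192, 0, 192),
                                 speedRange = c(20, 200), radius = 1.5,
                                 lengthRange = c(40, 90), inPlane = FALSE) {
  withSeed(seed, {
    rows <- vector("list", n)
    ext <- domain[c(2, 4, 6)] - domain[c(1, 3, 5)]
    for (i in seq_len(n)) {
      repeat {
        start <- domain[c(1, 3, 5)] + c(runif(1, 0.15, 0.85) * ext[1],
                                        runif(1, 0.1, 0.9) * ext[2],
                                        runif(1, 0.1, 0.9) * ext[3])
        dz <- if (inPlane) 0 else runif(1, -1, 1)
        ang <- runif(1, 0, 2 * pi)
        dir <- c(dz, sqrt(1 - dz^2) * cos(ang), sqrt(1 - dz^2) * sin(ang))
        len <- runif(1, lengthRange[1], lengthRange[2])
        end <- start + dir * len
        if (all(end >= domain[c(1, 3, 5)] + 2) &&
            all(end <= domain[c(2, 4, 6)] - 2)) break
      }
      rows[[i]] <- data.frame(id = i, parent = NA_integer_,
                              z0 = start[1], x0 = start[2], y0 = start[3],
                              z1 = end[1], x1 = end[2], y1 = end[3],
                              radius = radius,
                              speed = runif(1, speedRange[1], speedRange[2]),
                              class = "capillary")
    }
    vesselTree(do.call(rbind, rows), flowSense = 1, domain = domain)
  })
}

#' Rasterize a vessel tree onto the acquisition grid
#'
#' Produces the ground-truth sidecar arrays on the (z, x, y) grid implied by
#' the tree domain and the voxel pitch: segment labels, speeds, axial
#' velocities, Doppler angles, the forward-model (wrapped) Doppler phase,
#' aliasing flags, per-voxel axis vectors and a compartment code
#' (0 background, 1 arteriole, 2 venule, 3 capillary).
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param params an \linkS4class{AcquisitionParams} (voxel pitch, timing).
#' @return list of truth arrays.
#' @export
rasterizeTree <- function(tree, params) {
  dom <- tree@domain
  pitch <- params@voxelPitch
  nd <- pmax(2L, as.integer(round((dom[c(2, 4, 6)] - dom[c(1, 3, 5)]) /
                                    pitch)))
  nz <- nd[1]; nx <- nd[2]; ny <- nd[3]
  lab <- array(0L, c(nz, nx, ny))
  comp <- array(0L, c(nz, nx, ny))
  speed <- array(0, c(nz, nx, ny))
  vz <- array(0, c(nz, nx, ny))
  thetaZ <- array(NA_real_, c(nz, nx, ny))
  axis <- array(0, c(nz, nx, ny, 3))
  best <- array(Inf, c(nz, nx, ny))
  segs <- tree@segments
  compCode <- c(arteriole = 1L, venule = 2L, capillary = 3L)
  ctr <- function(i, k) dom[2 * k - 1] + (i - 0.5) * pitch[k]
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    p0 <- c(s$z0, s$x0, s$y0); p1 <- c(s$z1, s$x1, s$y1)
    d <- p1 - p0
    len <- sqrt(sum(d^2))
    if (len < 1e-9) next
    u <- d / len
    rad <- max(s$radius, 0.55 * min(pitch))  # thin capillaries cover >=1 voxel
    lo <- pmin(p0, p1) - rad - pitch
    hi <- pmax(p0, p1) + rad + pitch
    iz <- which(ctr(seq_len(nz), 1) >= lo[1] & ctr(seq_len(nz), 1) <= hi[1])
    ix <- which(ctr(seq_len(nx), 2) >= lo[2] & ctr(seq_len(nx), 2) <= hi[2])
    iy <- which(ctr(seq_len(ny), 3) >= lo[3] & ctr(seq_len(ny), 3) <= hi[3])
    if (!length(iz) || !length(ix) || !length(iy)) next
    gz <- ctr(iz, 1); gx <- ctr(ix, 2); gy <- ctr(iy, 3)
    pz <- array(gz, c(length(iz), length(ix), length(iy)))
    px <- array(rep(gx, each = length(iz)), c(length(iz), length(ix), length(iy)))
    py <- array(rep(gy, each = length(iz) * length(ix)),
                c(length(iz), length(ix), length(iy)))
    t <- (pz - p0[1]) * u[1] + (px - p0[2]) * u[2] + (py - p0[3]) * u[3]
    t <- pmin(pmax(t, 0), len)
    dz <- pz - (p0[1] + t * u[1])
    dx <- px - (p0[2] + t * u[2])
    dy <- py - (p0[3] + t * u[3])
    dist <- sqrt(dz^2 + dx^2 + dy^2)
    inside <- dist <= rad
    if (!any(inside)) next
    sub <- as.matrix(expand.grid(iz, ix, iy))[which(inside), , drop = FALSE]
    dsub <- dist[inside]
    lin <- sub[, 1] + nz * (sub[, 2] - 1L) + nz * nx * (sub[, 3] - 1L)
    win <- dsub < best[lin]
    lin <- lin[win]; dsub <- dsub[win]
    best[lin] <- dsub
    lab[lin] <- s$id
    comp[lin] <- compCode[[s$class]]
    speed[lin] <- s$speed
    vzSeg <- tree@flowSense * s$speed * u[1]
    vz[lin] <- vzSeg
    thetaZ[lin] <- acos(min(1, abs(u[1]))) * 180 / pi
    for (k in 1:3) axis[lin + (k - 1L) * nz * nx * ny] <- u[k]
  }
  dphiRaw <- 4 * pi * params@nTissue * vz * params@dtODT / params@lambda0
  list(label = lab, compartment = comp, speed = speed, vz = vz,
       thetaZ = thetaZ, dphi = wrapPhase(dphiRaw),
       aliased = array(abs(dphiRaw) > pi, dim(lab)), axis = axis,
       radiusVox = best)
}

#' Simulate a complex OCT acquisition of a vessel tree
#'
#' Synthesizes the complex A-line field on the (z, x, r, y) grid. The A-scan
#' at fast-axis index x of repeat frame r is acquired at time
#' r*dtOCA + x*dtODT; a voxel moving with axial velocity v_z advances its
#' phase at 4*pi*n*v_z/lambda0 rad/s, so adjacent A-scans differ by the
#' Doppler phase 4*pi*n*v_z*dtODT/lambda0, wrapped physically to (-pi, pi]
#' (aliased voxels are flagged in the sidecar, never clipped). With speckle
#' enabled the envelope is a complex circular Gaussian, amplitude-scaled by
#' scatterer density (lumen brighter than parenchyma), correlated along the
#' fast axis (beam oversampling) and decorrelating across repeats at a rate
#' increasing with flow speed; without speckle the envelope is the
#' deterministic density map, which makes the forward phase model exact.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param params an \linkS4class{AcquisitionParams}.
#' @param noise list: speckle (logical), lumenContrast (default 3),
#'   additive (complex noise sd), phaseNoise (per-voxel phase jitter sd,
#'   rad), decorrLength (um; repeat-to-repeat decorrelation scale).
#' @param seed integer seed.
#' @return a \linkS4class{ComplexAcquisition} with filled truth sidecar.
#' @export
simulateAcquisition <- function(tree, params, noise = list(), seed = 1L) {
  nz0 <- list(speckle = TRUE, lumenContrast = 3, additive = 0.05,
              phaseNoise = 0, decorrLength = 10)
  no <- modifyList(nz0, noise)
  if (no$additive < 0 || no$phaseNoise < 0)
    stop("noise levels must be >= 0")
  truth <- rasterizeTree(tree, params)
  d <- dim(truth$label)
  nzv <- d[1]; nxv <- d[2]; nyv <- d[3]
  nr <- params@nRepeats
  omega <- 4 * pi * params@nTissue * truth$vz / params@lambda0  # rad/s
  amp <- 1 + (no$lumenContrast - 1) * (truth$label > 0L)
  xidx <- array(rep(0:(nxv - 1), each = nzv), d)
  phiX <- omega * xidx * params@dtODT
  field <- array(complex(real = 0), c(nzv, nxv, nr, nyv))
  withSeed(seed, {
    cg <- function() {
      complex(real = rnorm(prod(d), sd = sqrt(0.5)),
              imaginary = rnorm(prod(d), sd = sqrt(0.5)))
    }
    smoothX <- function(v) {
      re <- sepFilter(array(Re(v), d), 1, c(0.25, 0.5, 0.25), 1)
      im <- sepFilter(array(Im(v), d), 1, c(0.25, 0.5, 0.25), 1)
      array(complex(real = re, imaginary = im), d)
    }
    if (no$speckle) {
      rho <- exp(-truth$speed * params@dtOCA / no$decorrLength)
      rho[truth$label == 0L] <- 1
      S <- array(cg(), d)
      for (r in seq_len(nr)) {
        if (r > 1L) S <- rho * S + sqrt(pmax(0, 1 - rho^2)) * array(cg(), d)
        env <- smoothX(S) * amp
        ph <- omega * (r - 1) * params@dtOCA + phiX
        field[, , r, ] <- env * exp(1i * ph)
      }
    } else {
      for (r in seq_len(nr)) {
        ph <- omega * (r - 1) * params@dtOCA + phiX
        field[, , r, ] <- amp * exp(1i * ph)
      }
    }
    if (no$phaseNoise > 0)
      field <- field * exp(1i * array(rnorm(length(field),
                                            sd = no$phaseNoise), dim(field)))
    if (no$additive > 0)
      field <- field +
        complex(real = rnorm(length(field), sd = no$additive * sqrt(0.5)),
                imaginary = rnorm(length(field), sd = no$additive * sqrt(0.5)))
  })
  truth$corrupted <- matrix(FALSE, nr, nyv)
  new("ComplexAcquisition", field = field, params = params, truth = truth)
}

#' Inject bulk-motion corruption into an acquisition
#'
#' Each frame (y, r) with a non-zero axial displacement delta-z acquires the
#' global phase 4*pi*n*delta-z/lambda0 and is resampled along z by the
#' corresponding sub-voxel shift; the frame-to-frame displacement rate adds
#' an intra-frame fast-axis phase ramp scaled by dtODT/dtOCA (which is why
#' bulk motion degrades angiography far more than Doppler flow). Frames
#' flagged in the trace are phase-scrambled with the trace's mixing
#' amplitude so they decorrelate from their neighbours. The sidecar's
#' corrupted-frame set is set to the flag set.
#'
#' @param acq a \linkS4class{ComplexAcquisition}.
#' @param trace a \linkS4class{MotionTrace} with (nRepeats x nY) entries.
#' @param seed seed for the scramble phases.
#' @param intraFrame also apply the fast-axis phase ramp implied by the
#'   frame-to-frame displacement rate (off by default; the Doppler pair
#'   spacing makes it ~100x weaker than the frame-to-frame effects).
#' @return the corrupted \linkS4class{ComplexAcquisition}.
#' @export
injectBulkMotion <- function(acq, trace, seed = 1L, intraFrame = FALSE) {
  d <- dim(acq@field)
  if (!all(dim(trace@deltaZ) == d[c(3, 4)]))
    stop("motion trace shape (", paste(dim(trace@deltaZ), collapse = "x"),
         ") does not match acquisition frames (", d[3], "x", d[4], ")")
  p <- acq@params
  field <- acq@field
  a <- trace@scrambleAmplitude
  withSeed(seed, {
    for (y in seq_len(d[4])) for (r in seq_len(d[3])) {
      dz <- trace@deltaZ[r, y]
      scr <- trace@scramble[r, y]
      if (dz == 0 && !scr) next
      fr <- field[, , r, y]
      if (dz != 0) {
        fr <- fr * exp(1i * 4 * pi * p@nTissue * dz / p@lambda0)
        s <- dz / p@voxelPitch[1]
        if (abs(s) > 1e-9) {
          d2 <- c(d[1], d[2], 1L)
          re <- .shiftSample(array(Re(fr), d2), d2, -s, 0, 0)
          im <- .shiftSample(array(Im(fr), d2), d2, -s, 0, 0)
          fr <- matrix(complex(real = re, imaginary = im), d[1], d[2])
        }
        rate <- if (intraFrame && r > 1L)
          (dz - trace@deltaZ[r - 1L, y]) / p@dtOCA else 0
        if (rate != 0) {
          ramp <- exp(1i * 4 * pi * p@nTissue * rate * p@dtODT / p@lambda0 *
                        (0:(d[2] - 1)))
          fr <- sweep(fr, 2, ramp, "*")
        }
      }
      if (scr && a > 0) {
        ## severe motion: the frame's structural envelope is displaced along
        ## the beam (drift during the B-scan) and the field is replaced by
        ## fresh speckle (uniform random phase, Rayleigh amplitude), so both
        ## phase and intensity decorrelate from the neighbouring frames
        npx <- d[1] * d[2]
        sh <- sample(c(-1L, 1L), 1L) * sample(seq.int(d[1] %/% 8L,
                                                      d[1] %/% 2L), 1L)
        env <- Mod(fr)[(((seq_len(d[1]) - 1L + sh) %% d[1]) + 1L), ]
        rnd <- env * matrix(complex(real = rnorm(npx, sd = sqrt(0.5)),
                                    imaginary = rnorm(npx, sd = sqrt(0.5))),
                            d[1], d[2])
        fr <- (1 - a) * fr + a * rnd
      }
      field[, , r, y] <- fr
    }
  })
  acq@field <- field
  acq@truth$corrupted <- trace@scramble
  acq
}

#' Orientation field from the ground-truth sidecar
#'
#' Convenience for phantom studies: the per-voxel Doppler angle and axis of
#' the rasterized tree, with confidence 1 on vessel voxels and 0 elsewhere.
#'
#' @param acq a \linkS4class{ComplexAcquisition} with truth sidecar.
#' @return an \linkS4class{OrientationField}.
#' @export
truthOrientation <- function(acq) {
  tr <- acq@truth
  conf <- array(as.numeric(tr$label > 0L), dim(tr$label))
  new("OrientationField", thetaZ = tr$thetaZ, axis = tr$axis,
      confidence = conf)
}
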