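## Synthetic FIB/SEM-like neuropil generator.
##
## The generator emulates the imaging substrate of a volume-EM synapse
## census: tubular dendritic shafts laid as smooth random walks, spines
## (cylindrical neck + ellipsoidal head) attached to them, and synaptic
## junctions rendered as two apposed electron-dense plates separated by a
## bright cleft. The postsynaptic plate is thick for asymmetric (AS) and
## thin for symmetric (SS) junctions, which is what makes the downstream
## "prominent vs thin PSD" classification operational. Background is bright
## and densities are dark, matching backscattered-electron contrast.
## Objects are laid in a domain extended beyond the stack and clipped at
## the faces, so border truncation is an emergent property of the geometry
## rather than an independently sampled flag.

.multiComboDef <- list(
  two_AS        = c(AS = 2, SS = 0),
  one_AS_one_SS = c(AS = 1, SS = 1),
  two_AS_one_SS = c(AS = 2, SS = 1),
  three_AS      = c(AS = 3, SS = 0),
  two_SS        = c(AS = 0, SS = 2),
  three_SS      = c(AS = 0, SS = 3),
  one_AS_two_SS = c(AS = 1, SS = 2)
)

.defaultMultiMix <- c(two_AS = 146, one_AS_one_SS = 84, two_AS_one_SS = 9,
                      three_AS = 6, two_SS = 6, three_SS = 2,
                      one_AS_two_SS = 1) / 254

.defaultGeometry <- function() list(
  background = 200, cytoplasm = 190, densityGray = 40,
  dendriteDiameter = c(0.3, 1.5),   # um
  dendriteStep = 150,               # nm, random-walk step
  dendriteTurnSd = 0.08,            # direction jitter per step
  neckRadius = 70,                  # nm
  neckLength = c(250, 500),         # nm
  headRadius = c(180, 260),         # nm, transverse semi-axis
  headElongation = 1.2,             # semi-axis along spine axis / transverse
  plateRadius = c(130, 180),        # nm
  preThickness = 20,                # nm, presynaptic density
  cleft = 20,                       # nm (at least one voxel when rendered)
  asPsd = c(40, 60),                # nm, AS postsynaptic plate thickness
  ssPsd = c(15, 25),                # nm, SS postsynaptic plate thickness
  boutonRadius = 180,               # nm
  minSynapseSep = 450,              # nm between synapses of different hosts
  spineSpacing = 500,               # nm along the host dendrite
  margin = 1000                     # nm of object domain beyond the stack
)

#' Construct a NeuropilSpec
#'
#' Parameter defaults are the layer-averaged values of the bundled juvenile
#' rat somatosensory-cortex census: synapse intensity 0.89 per um^3, 90.28%
#' AS, 83.61% / 25.47% of AS / SS on spines, 97.02% of axospinous synapses
#' on the head, 5.57% of spines with multiple synapses (mixed per the
#' bundled single/multiple table), 58.98% of shaft targets on spiny
#' dendrites. The default stack geometry is 2048 x 1536 x 255 voxels at
#' 4 x 4 x 20 nm.
#'
#' @param volumeExtent stack extent in um (x, y, z).
#' @param voxelSize voxel size in nm.
#' @param synapseIntensity expected synapses per um^3.
#' @param asFraction proportion of AS among synapses.
#' @param spineTargetFractionAS,spineTargetFractionSS proportion of AS (SS)
#'   targeting spines.
#' @param headFraction proportion of axospinous synapses on the head.
#' @param multiSynapseFraction proportion of spines with >1 synapse.
#' @param multiMix named weights over multi-synapse combinations; names as
#'   in `profileSpines` categories.
#' @param singleASFraction AS share among single-synapse spines.
#' @param spinyShaftFraction spiny share among shaft-targeting synapses.
#' @param shrinkage linear tissue shrinkage fraction in [0, 1).
#' @param noise c(gaussian_sd, dark_current) in gray levels.
#' @param geometry named list overriding rendering geometry entries; see
#'   the vignette for the full list and units.
#' @param rngSeed integer seed; generation is fully reproducible.
#' @return A \linkS4class{NeuropilSpec}.
#' @examples
#' sp <- neuropilSpec(volumeExtent = c(2, 2, 1), rngSeed = 7L)
#' sp
#' @export
neuropilSpec <- function(volumeExtent = c(8.192, 6.144, 5.10),
                         voxelSize = c(4, 4, 20),
                         synapseIntensity = 0.89,
                         asFraction = 0.9028,
                         spineTargetFractionAS = 0.8361,
                         spineTargetFractionSS = 0.2547,
                         headFraction = 0.9702,
                         multiSynapseFraction = 0.0557,
                         multiMix = .defaultMultiMix,
                         singleASFraction = 0.9865,
                         spinyShaftFraction = 0.5898,
                         shrinkage = 0,
                         noise = c(12, 3),
                         geometry = list(),
                         rngSeed = 1L) {
  geo <- .defaultGeometry()
  stopifnot(all(names(geometry) %in% names(geo)))
  geo[names(geometry)] <- geometry
  mm <- multiMix / sum(multiMix)
  stopifnot(all(names(mm) %in% names(.multiComboDef)))
  new("NeuropilSpec",
      volumeExtent = as.numeric(volumeExtent), voxelSize = as.numeric(voxelSize),
      synapseIntensity = synapseIntensity, asFraction = asFraction,
      spineTargetFractionAS = spineTargetFractionAS,
      spineTargetFractionSS = spineTargetFractionSS,
      headFraction = headFraction, multiSynapseFraction = multiSynapseFraction,
      multiMix = mm, singleASFraction = singleASFraction,
      spinyShaftFraction = spinyShaftFraction, shrinkage = shrinkage,
      noise = as.numeric(noise), geometry = geo, rngSeed = as.integer(rngSeed))
}

setMethod("show", "NeuropilSpec", function(object) {
  cat(sprintf("NeuropilSpec: %.3g x %.3g x %.3g um at %g x %g x %g nm voxels\n",
              object@volumeExtent[1], object@volumeExtent[2], object@volumeExtent[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  %.3g synapses/um^3, AS fraction %.4f, multi-synapse spines %.4f, seed %d\n",
              object@synapseIntensity, object@asFraction,
              object@multiSynapseFraction, object@rngSeed))
})

## ---- low-level voxel stamping ------------------------------------------

.candGrid <- function(dims, vx, lo, hi) {
  i0 <- pmax(1L, as.integer(ceiling(lo / vx + 0.5)))
  i1 <- pmin(dims, as.integer(floor(hi / vx + 0.5)))
  if (any(i1 < i0)) return(NULL)
  ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
  ni <- length(ii); nj <- length(jj); nk <- length(kk)
  I <- rep.int(ii, nj * nk)
  J <- rep.int(rep.int(jj, rep.int(ni, nj)), nk)
  K <- rep.int(kk, rep.int(ni * nj, nk))
  list(I = I, J = J, K = K,
       X = (I - 0.5) * vx[1], Y = (J - 0.5) * vx[2], Z = (K - 0.5) * vx[3])
}

.linIdx <- function(dims, I, J, K)
  ((K - 1L) * dims[2] + (J - 1L)) * dims[1] + I

.paint <- function(scene, g, sel, gray, label, onlyBg = FALSE) {
  if (is.null(g) || !any(sel)) return(invisible(NULL))
  idx <- .linIdx(scene$dims, g$I[sel], g$J[sel], g$K[sel])
  if (onlyBg) {
    # claim only unlabelled voxels: earlier objects keep their geometry
    idx <- idx[scene$labels[idx] == 0L]
    if (!length(idx)) return(invisible(NULL))
  }
  .paint_gray(scene$img, idx, gray)
  if (!is.null(label)) .paint_label(scene$labels, idx, as.integer(label))
  invisible(NULL)
}

.stampBall <- function(scene, c0, r, gray, label = NULL, onlyBg = FALSE) {
  g <- .candGrid(scene$dims, scene$vx, c0 - r, c0 + r)
  if (is.null(g)) return(invisible(NULL))
  sel <- (g$X - c0[1])^2 + (g$Y - c0[2])^2 + (g$Z - c0[3])^2 <= r * r
  .paint(scene, g, sel, gray, label, onlyBg)
}

.stampCapsule <- function(scene, p1, p2, r, gray, label = NULL, onlyBg = FALSE) {
  lo <- pmin(p1, p2) - r; hi <- pmax(p1, p2) + r
  g <- .candGrid(scene$dims, scene$vx, lo, hi)
  if (is.null(g)) return(invisible(NULL))
  d <- p2 - p1; L <- sqrt(sum(d^2))
  a <- if (L > 0) d / L else c(1, 0, 0)
  px <- g$X - p1[1]; py <- g$Y - p1[2]; pz <- g$Z - p1[3]
  t <- pmin(pmax(px * a[1] + py * a[2] + pz * a[3], 0), L)
  sel <- (px - t * a[1])^2 + (py - t * a[2])^2 + (pz - t * a[3])^2 <= r * r
  .paint(scene, g, sel, gray, label, onlyBg)
}

.stampEllipsoid <- function(scene, c0, axis, ra, rr, gray, label = NULL,
                            onlyBg = FALSE) {
  r <- max(ra, rr)
  g <- .candGrid(scene$dims, scene$vx, c0 - r, c0 + r)
  if (is.null(g)) return(invisible(NULL))
  px <- g$X - c0[1]; py <- g$Y - c0[2]; pz <- g$Z - c0[3]
  t <- px * axis[1] + py * axis[2] + pz * axis[3]
  r2 <- px^2 + py^2 + pz^2 - t^2
  sel <- t^2 / ra^2 + r2 / rr^2 <= 1
  .paint(scene, g, sel, gray, label, onlyBg)
}

# A disc-shaped slab between offsets t0..t1 along unit normal `n` relative
# to centre c0. Slabs thinner than the voxel projection along `n` are
# widened (in the direction of `grow`: -1 inward, +1 outward, 0 symmetric)
# so the plate is never lost between voxel centres.
.stampPlate <- function(scene, c0, n, radius, t0, t1, gray, label = NULL,
                        grow = 0) {
  proj <- sum(abs(n) * scene$vx)
  w <- t1 - t0
  if (w < proj) {
    pad <- proj - w
    if (grow < 0) t0 <- t0 - pad
    else if (grow > 0) t1 <- t1 + pad
    else { t0 <- t0 - pad / 2; t1 <- t1 + pad / 2 }
  }
  reach <- max(abs(t0), abs(t1)) + radius
  g <- .candGrid(scene$dims, scene$vx, c0 - reach, c0 + reach)
  if (is.null(g)) return(invisible(NULL))
  px <- g$X - c0[1]; py <- g$Y - c0[2]; pz <- g$Z - c0[3]
  t <- px * n[1] + py * n[2] + pz * n[3]
  r2 <- px^2 + py^2 + pz^2 - t^2
  sel <- t >= t0 & t <= t1 & r2 <= radius^2
  .paint(scene, g, sel, gray, label)
}

## ---- geometry helpers ---------------------------------------------------

.randUnit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

.unitPerp <- function(a) {
  repeat {
    u <- .randUnit()
    u <- u - sum(u * a) * a
    n <- sqrt(sum(u^2))
    if (n > 0.2) return(u / n)
  }
}

# Smooth random-walk polyline through the extended domain, guaranteed to
# pass through the stack interior (it starts there). When an obstacle
# cloud is supplied (centreline samples of already-laid dendrites with
# per-point clearance radii), each step steers around blocked positions
# with increasing deflection and the walk ends where no clear step
# exists, so dendrites never interpenetrate.
.dendritePath <- function(extentNm, margin, step, turnSd,
                          obstacles = NULL, obstacleClear = NULL) {
  lo <- rep(-margin, 3); hi <- extentNm + margin
  blocked <- function(p) {
    if (is.null(obstacles) || nrow(obstacles) == 0L) return(FALSE)
    d2 <- (obstacles[, 1] - p[1])^2 + (obstacles[, 2] - p[2])^2 +
      (obstacles[, 3] - p[3])^2
    any(d2 < obstacleClear^2)
  }
  # start anywhere in the extended domain so tube coverage (and hence the
  # space available to spines) is spatially homogeneous across the stack
  start <- NULL
  for (a in 1:60) {
    cand <- stats::runif(3, lo, hi)
    if (!blocked(cand)) { start <- cand; break }
  }
  if (is.null(start)) return(matrix(numeric(0), 0, 3))
  dir0 <- .randUnit()
  walk <- function(p0, d) {
    pts <- list()
    p <- p0
    for (i in seq_len(5000L)) {
      moved <- FALSE
      for (a in 1:8) {
        dn <- d + stats::rnorm(3, 0, turnSd * a)
        dn <- dn / sqrt(sum(dn^2))
        pn <- p + dn * step
        outside <- any(pn < lo) || any(pn > hi)
        if (!outside && blocked(pn)) next
        if (outside) return(if (length(pts)) do.call(rbind, pts)
                            else matrix(numeric(0), 0, 3))
        d <- dn; p <- pn
        pts[[length(pts) + 1L]] <- p
        moved <- TRUE
        break
      }
      if (!moved) break
    }
    if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 3)
  }
  fwd <- walk(start, dir0)
  bwd <- walk(start, -dir0)
  rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
        matrix(start, 1, 3), fwd)
}

.insideVolume <- function(p, extentNm) all(p >= 0) && all(p <= extentNm)


.pathTangent <- function(path, i) {
  i2 <- min(nrow(path), i + 1L); i1 <- max(1L, i - 1L)
  d <- path[i2, ] - path[i1, ]
  n <- sqrt(sum(d^2))
  if (n == 0) c(1, 0, 0) else d / n
}

# For each spine id: TRUE when the spine has no in-volume voxels, touches
# the stack border (emergent truncation), or is 26-adjacent to its parent
# dendrite's label. One scan of the label volume for all spines.
.spinesConnected <- function(scene, spineIds, parentIds) {
  lab <- scene$labels
  d <- scene$dims; nx <- d[1]; ny <- d[2]; nz <- d[3]
  idx <- which(lab >= min(spineIds) & lab <= max(spineIds))
  ok <- rep(TRUE, length(spineIds))
  if (!length(idx)) return(ok)
  labv <- lab[idx]
  bySpine <- split(idx, labv)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  for (s in seq_along(spineIds)) {
    vox <- bySpine[[as.character(spineIds[s])]]
    if (is.null(vox)) next
    i <- (vox - 1L) %% nx + 1L
    j <- ((vox - 1L) %/% nx) %% ny + 1L
    k <- (vox - 1L) %/% (nx * ny) + 1L
    if (any(i == 1L | i == nx | j == 1L | j == ny | k == 1L | k == nz)) next
    found <- FALSE
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs$di[r]; jj <- j + offs$dj[r]; kk <- k + offs$dk[r]
      keep <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny & kk >= 1L & kk <= nz
      if (!any(keep)) next
      nb <- lab[((kk[keep] - 1L) * ny + (jj[keep] - 1L)) * nx + ii[keep]]
      if (any(nb == parentIds[s])) { found <- TRUE; break }
    }
    ok[s] <- found
  }
  ok
}

# Would a junction (two plates + cleft) at `center` with outward normal
# `u` and disc radius `plateR` stamp into any of the structures sampled by
# `pts` (with local radii `ptsR`)? Conflicts are tested in plate-aligned
# coordinates: axial reach covers postsynaptic density, cleft and
# presynaptic density; lateral reach is the disc radius.
.plateConflict <- function(center, u, plateR, pts, ptsR) {
  if (!nrow(pts)) return(FALSE)
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]; dz <- pts[, 3] - center[3]
  a <- dx * u[1] + dy * u[2] + dz * u[3]
  l <- sqrt(pmax(dx^2 + dy^2 + dz^2 - a^2, 0))
  any(a > -100 - ptsR & a < 90 + ptsR & l < plateR + ptsR + 15)
}

# minimum distance from points `p` (n x 3) to a cloud of centreline samples
.minDistToCloud <- function(p, cloud) {
  if (nrow(cloud) == 0L) return(rep(Inf, nrow(p)))
  vapply(seq_len(nrow(p)), function(i) {
    dx <- cloud[, 1] - p[i, 1]; dy <- cloud[, 2] - p[i, 2]; dz <- cloud[, 3] - p[i, 3]
    sqrt(min(dx * dx + dy * dy + dz * dz))
  }, numeric(1))
}

## ---- scene planning -----------------------------------------------------

# Draw the synapse plan: number of synapses, their types, targets and the
# grouping of axospinous synapses into spines. Spine-synapse types come
# from the single/multiple profile machinery; the AS share of shaft
# synapses is derived so the overall AS fraction equals `asFraction` in
# expectation.
.planSynapses <- function(spec) {
  nominal <- prod(spec@volumeExtent)
  nSyn <- stats::rpois(1L, spec@synapseIntensity * nominal)
  pSpine <- spec@asFraction * spec@spineTargetFractionAS +
    (1 - spec@asFraction) * spec@spineTargetFractionSS
  m <- spec@multiSynapseFraction
  mix <- spec@multiMix
  sizes <- vapply(.multiComboDef[names(mix)], sum, numeric(1))
  nASmix <- vapply(.multiComboDef[names(mix)], function(x) x[["AS"]], numeric(1))
  ESynPerSpine <- (1 - m) + m * sum(mix * sizes)
  EASPerSpine <- (1 - m) * spec@singleASFraction + m * sum(mix * nASmix)
  pASspine <- EASPerSpine / ESynPerSpine
  pASshaft <- if (pSpine >= 1) 0 else
    min(1, max(0, (spec@asFraction - pSpine * pASspine) / (1 - pSpine)))

  nShaft <- stats::rbinom(1L, nSyn, 1 - pSpine)
  nSpineSyn <- nSyn - nShaft

  spines <- list()
  left <- nSpineSyn
  while (left > 0L) {
    multi <- stats::runif(1) < m && left >= 2L
    if (multi) {
      repeat {
        combo <- sample(names(mix), 1L, prob = mix)
        if (sum(.multiComboDef[[combo]]) <= left) break
      }
      types <- rep(c("AS", "SS"), .multiComboDef[[combo]])
    } else {
      types <- if (stats::runif(1) < spec@singleASFraction) "AS" else "SS"
    }
    types <- sample(types)
    spines[[length(spines) + 1L]] <- types
    left <- left - length(types)
  }
  shaftTypes <- ifelse(stats::runif(nShaft) < pASshaft, "AS", "SS")
  shaftSpiny <- stats::runif(nShaft) < spec@spinyShaftFraction
  list(nSyn = nSyn, spineTypes = spines, shaftTypes = shaftTypes,
       shaftSpiny = shaftSpiny)
}

## ---- the generator ------------------------------------------------------

#' Generate a synthetic neuropil stack with ground truth
#'
#' Draws the synapse population (Poisson in the nominal volume), lays
#' dendrites and spines, places every synaptic junction as a two-plate
#' (pre/postsynaptic density) structure with the postsynaptic plate
#' thickness drawn from the AS or SS range, renders the gray-value stack
#' (bright background, dark densities), adds Gaussian and dark-current
#' noise last, and returns the image together with an exhaustive
#' \linkS4class{GroundTruth}. With `render = FALSE` only the object ledger
#' is produced (the label volume is a placeholder), which is the cheap path
#' for statistical calibration of the generator itself.
#'
#' @param spec a \linkS4class{NeuropilSpec}.
#' @param render render the gray-value and label volumes (TRUE) or produce
#'   the ledger only (FALSE).
#' @return A list with elements `volume` (\linkS4class{VoxelVolume} or NULL
#'   when `render = FALSE`) and `truth` (\linkS4class{GroundTruth}).
#' @examples
#' sp <- neuropilSpec(volumeExtent = c(2, 2, 1.5), voxelSize = c(10, 10, 25),
#'                    synapseIntensity = 3, rngSeed = 11L)
#' out <- generateStack(sp)
#' table(ledger(out$truth)$kind)
#' @export
generateStack <- function(spec, render = TRUE) {
  stopifnot(is(spec, "NeuropilSpec"))
  validObject(spec)
  geo <- spec@geometry
  extentNm <- spec@volumeExtent * 1000
  if (any(extentNm < max(geo$dendriteDiameter) * 1000))
    stop("degenerate input: volume too small to host one dendrite")
  set.seed(spec@rngSeed)

  plan <- .planSynapses(spec)
  nSpines <- length(plan$spineTypes)
  nShaft <- length(plan$shaftTypes)
  nShaftSpiny <- sum(plan$shaftSpiny)
  nShaftBald <- nShaft - nShaftSpiny

  ## ---- dendrites
  dendrites <- list()
  # existing centreline samples and their radii, for obstacle avoidance
  denObstacles <- function() {
    if (!length(dendrites)) return(list(p = NULL, r = NULL))
    list(p = do.call(rbind, lapply(dendrites, function(d) d$path)),
         r = unlist(lapply(dendrites, function(d) rep(d$radius, nrow(d$path)))))
  }
  addDendrite <- function(spiny) {
    for (try in 1:40) {
      radius <- stats::runif(1, geo$dendriteDiameter[1], geo$dendriteDiameter[2]) * 500
      obs <- denObstacles()
      path <- .dendritePath(extentNm, geo$margin, geo$dendriteStep,
                            geo$dendriteTurnSd, obstacles = obs$p,
                            obstacleClear = if (is.null(obs$r)) NULL
                                            else obs$r + radius + 40)
      if (nrow(path) < 8L) next
      mid <- (path[-1L, , drop = FALSE] + path[-nrow(path), , drop = FALSE]) / 2
      insideSeg <- mid[, 1] >= 0 & mid[, 1] <= extentNm[1] &
        mid[, 2] >= 0 & mid[, 2] <= extentNm[2] &
        mid[, 3] >= 0 & mid[, 3] <= extentNm[3]
      insideLen <- sum(insideSeg) * geo$dendriteStep
      if (insideLen < 1000) next
      dendrites[[length(dendrites) + 1L]] <<- list(
        path = path, radius = radius, spiny = spiny, insideLen = insideLen)
      return(TRUE)
    }
    FALSE
  }

  spineCapacity <- function(d) as.integer(max(0, floor(d$insideLen / geo$spineSpacing)))
  needSpiny <- nSpines > 0L || nShaftSpiny > 0L
  while (needSpiny &&
         sum(vapply(Filter(function(d) d$spiny, dendrites), spineCapacity, integer(1)),
             0L) < ceiling(nSpines * 1.2) + 1L) {
    if (!addDendrite(TRUE)) break
    if (length(dendrites) > 200L) break
  }
  nBaldDen <- if (nShaftBald > 0L) max(1L, ceiling(nShaftBald / 5)) else 0L
  for (i in seq_len(nBaldDen)) addDendrite(FALSE)
  if (length(dendrites) == 0L) addDendrite(nSpines > 0L)
  if (length(dendrites) == 0L)
    stop("degenerate input: could not lay any dendrite in the volume")

  denCloud <- do.call(rbind, lapply(dendrites, function(d) d$path))
  denCloudRadius <- unlist(lapply(dendrites, function(d) rep(d$radius, nrow(d$path))))
  denCloudOwner <- rep(seq_along(dendrites),
                       vapply(dendrites, function(d) nrow(d$path), integer(1)))
  spinyIdx <- which(vapply(dendrites, function(d) d$spiny, logical(1)))
  baldIdx <- which(!vapply(dendrites, function(d) d$spiny, logical(1)))

  ## ---- spines
  ## Strict non-interpenetration: a spine is accepted only when its whole
  ## neck and head clear every foreign dendrite and every earlier spine;
  ## otherwise it is re-drawn, and after the retry budget it is dropped
  ## together with its planned synapses (the ledger always describes the
  ## realized population). Interpenetrating structures would make
  ## spine-to-parent tracing through the label volume ill-defined.
  spineGeo <- list()
  spineTypes <- list()
  headCenters <- matrix(numeric(0), 0, 3)
  spineCloud <- matrix(numeric(0), 0, 3)   # occupied spine points
  spineCloudR <- numeric(0)                # their local radii
  spineCloudOwner <- integer(0)            # spine index of each point
  hostOf <- integer(0)
  if (nSpines > 0L) {
    hostW <- vapply(dendrites[spinyIdx], function(d) d$insideLen, numeric(1))
    for (s in seq_len(nSpines)) {
      for (try in 1:150) {
        host <- spinyIdx[sample.int(length(spinyIdx), 1L, prob = hostW)]
        den <- dendrites[[host]]
        i <- sample.int(nrow(den$path), 1L)
        tang <- .pathTangent(den$path, i)
        u <- .unitPerp(tang)
        attach <- den$path[i, ] + u * den$radius
        neckLen <- stats::runif(1, geo$neckLength[1], geo$neckLength[2])
        rr <- stats::runif(1, geo$headRadius[1], geo$headRadius[2])
        ra <- rr * geo$headElongation
        headC <- attach + u * (neckLen + ra * 0.8)
        if (!.insideVolume(headC, extentNm)) next
        # either the attachment region is genuinely in the volume (the
        # parent is then present around the neck root) or the whole
        # attachment lies outside (the neck then crosses a face and the
        # spine is recognizably truncated); the in-between sliver would
        # leave a spine whose parent has no in-volume voxels at the root
        if (!.insideVolume(den$path[i, ], extentNm) &&
            .insideVolume(attach, extentNm)) next
        if (nrow(headCenters) &&
            min(.minDistToCloud(matrix(headC, 1, 3), headCenters)) < 400) next
        steps <- seq(0.2, 1, by = 0.2)
        probe <- rbind(t(vapply(steps, function(f) attach + u * (neckLen * f),
                                numeric(3))),
                       headC, headC + u * ra)
        probeR <- c(rep(geo$neckRadius, length(steps)), rr, rr)
        ok <- TRUE
        for (f in seq_along(dendrites)) {
          if (f == host) next
          df <- dendrites[[f]]
          dm <- .minDistToCloud(probe, df$path)
          if (any(dm < df$radius + probeR + 10)) { ok <- FALSE; break }
        }
        if (ok && nrow(spineCloud)) {
          for (q in seq_len(nrow(probe))) {
            dd <- sqrt((spineCloud[, 1] - probe[q, 1])^2 +
                       (spineCloud[, 2] - probe[q, 2])^2 +
                       (spineCloud[, 3] - probe[q, 3])^2)
            if (any(dd < spineCloudR + probeR[q] + 10)) { ok <- FALSE; break }
          }
        }
        if (!ok) next
        spineGeo[[length(spineGeo) + 1L]] <-
          list(attach = attach, dir = u, neckLen = neckLen,
               headC = headC, ra = ra, rr = rr, host = host)
        spineTypes[[length(spineTypes) + 1L]] <- plan$spineTypes[[s]]
        headCenters <- rbind(headCenters, headC)
        spineCloud <- rbind(spineCloud, probe)
        spineCloudR <- c(spineCloudR, probeR)
        spineCloudOwner <- c(spineCloudOwner, rep(length(spineGeo), nrow(probe)))
        hostOf <- c(hostOf, host)
        break
      }
    }
  }

  ## ---- synapse placement
  synCenters <- matrix(numeric(0), 0, 3)
  synSpineOf <- integer(0)   # spine index of each placed synapse (0 = shaft)
  synapses <- list()
  geoPsd <- function(type)
    if (type == "AS") stats::runif(1, geo$asPsd[1], geo$asPsd[2])
    else stats::runif(1, geo$ssPsd[1], geo$ssPsd[2])

  addSynapse <- function(center, normal, type, target, spineId, dendId, plateR) {
    synapses[[length(synapses) + 1L]] <<- list(
      center = center, normal = normal, type = type, target = target,
      spine = spineId, dendrite = dendId,
      plateR = plateR, psd = geoPsd(type))
    synCenters <<- rbind(synCenters, center)
    synSpineOf <<- c(synSpineOf, if (is.na(spineId)) 0L else spineId)
  }

  # distance to the nearest synapse of a *different* postsynaptic element;
  # multiple synapses on one spine are kept apart by the angle rule instead
  sepToOthers <- function(center, ownSpine) {
    keep <- synSpineOf != ownSpine | ownSpine == 0L
    if (ownSpine == 0L) keep <- rep(TRUE, length(synSpineOf))
    if (!any(keep)) return(Inf)
    .minDistToCloud(matrix(center, 1, 3), synCenters[keep, , drop = FALSE])
  }

  # a junction must not stamp into structures other than its own
  # postsynaptic element (and, for shaft synapses, its host shaft)
  junctionClear <- function(center, u, plateR, ownSpine, ownDendrite) {
    keepD <- denCloudOwner != ownDendrite
    if (any(keepD) &&
        .plateConflict(center, u, plateR, denCloud[keepD, , drop = FALSE],
                       denCloudRadius[keepD])) return(FALSE)
    if (length(spineCloudOwner)) {
      keepS <- spineCloudOwner != ownSpine
      if (any(keepS) &&
          .plateConflict(center, u, plateR, spineCloud[keepS, , drop = FALSE],
                         spineCloudR[keepS])) return(FALSE)
    }
    TRUE
  }

  for (s in seq_along(spineGeo)) {
    sg <- spineGeo[[s]]
    types <- spineTypes[[s]]
    k <- length(types)
    dirs <- list()
    for (m in seq_len(k)) {
      onHead <- stats::runif(1) < spec@headFraction
      plateR <- stats::runif(1, geo$plateRadius[1], geo$plateRadius[2])
      for (try in 1:60) {
        if (onHead) {
          u <- .randUnit()
          if (length(dirs) && any(vapply(dirs, function(v) sum(v * u), numeric(1)) >
                                  cos(100 * pi / 180))) next
          ax <- sg$dir
          tt <- sum(u * ax)
          rad <- 1 / sqrt(tt^2 / sg$ra^2 + max(1 - tt^2, 1e-9) / sg$rr^2)
          center <- sg$headC + u * rad
          normal <- u
        } else {
          tpos <- stats::runif(1, 0.25, 0.75)
          base <- sg$attach + sg$dir * (sg$neckLen * tpos)
          u <- .unitPerp(sg$dir)
          center <- base + u * geo$neckRadius
          normal <- u
        }
        if (!.insideVolume(center, extentNm)) next
        if (nrow(synCenters) &&
            sepToOthers(center, s) < geo$minSynapseSep) next
        if (!junctionClear(center, normal, plateR, s, 0L)) next
        dirs[[length(dirs) + 1L]] <- if (onHead) u else NULL
        addSynapse(center, normal, types[m],
                   if (onHead) "head" else "neck", s, sg$host, plateR)
        break
      }
    }
  }

  if (nShaft > 0L) {
    for (m in seq_len(nShaft)) {
      wantSpiny <- plan$shaftSpiny[m]
      pool <- if (wantSpiny && length(spinyIdx)) spinyIdx
              else if (!wantSpiny && length(baldIdx)) baldIdx
              else seq_along(dendrites)
      plateR0 <- stats::runif(1, geo$plateRadius[1], geo$plateRadius[2])
      for (try in 1:80) {
        host <- pool[sample.int(length(pool), 1L)]
        den <- dendrites[[host]]
        # a junction on a shaft is no wider than the shaft itself; an
        # uncapped tangent disc on a thin tube would hang into the
        # neighbouring neuropil and fuse with nearby junctions
        plateR <- min(plateR0, max(100, 0.95 * den$radius))
        i <- sample.int(nrow(den$path), 1L)
        tang <- .pathTangent(den$path, i)
        u <- .unitPerp(tang)
        center <- den$path[i, ] + u * den$radius
        if (!.insideVolume(center, extentNm)) next
        if (nrow(synCenters)) {
          dmin <- .minDistToCloud(matrix(center, 1, 3), synCenters)
          # tangent plates curve around the host, so neighbouring shaft
          # junctions need clearance beyond the plate diameter however
          # small the configured separation floor is
          if (dmin < max(geo$minSynapseSep, 2 * plateR + 120)) next
        }
        if (!junctionClear(center, u, plateR, 0L, host)) next
        addSynapse(center, u, plan$shaftTypes[m], "shaft", NA_integer_, host, plateR)
        break
      }
    }
  }

  ## ---- ids and ledger skeleton
  nDen <- length(dendrites)
  denIds <- seq_len(nDen)
  spineIds <- nDen + seq_along(spineGeo)
  synIds <- nDen + length(spineGeo) + seq_along(synapses)

  ## ---- rendering
  if (render) {
    dims <- pmax(2L, as.integer(round(extentNm / spec@voxelSize)))
    scene <- new.env(parent = emptyenv())
    scene$dims <- dims
    scene$vx <- spec@voxelSize
    scene$img <- array(geo$background, dim = dims)
    scene$labels <- array(0L, dim = dims)

    for (d in seq_len(nDen)) {
      den <- dendrites[[d]]
      step <- max(den$radius / 2, spec@voxelSize[3])
      n <- nrow(den$path)
      keep <- unique(c(seq(1L, n, by = max(1L, round(step / geo$dendriteStep))), n))
      for (i in keep)
        .stampBall(scene, den$path[i, ], den$radius, geo$cytoplasm, denIds[d])
    }
    for (s in seq_along(spineGeo)) {
      sg <- spineGeo[[s]]
      # the neck root claims a plug inside the parent tube, making the
      # spine-to-parent contact surface decisively larger than any
      # incidental contact with a brushing foreign structure; the rest of
      # the spine claims only unlabelled voxels so foreign geometry is
      # preserved
      rootDepth <- min(100, dendrites[[sg$host]]$radius * 0.6)
      .stampCapsule(scene, sg$attach - sg$dir * rootDepth, sg$attach,
                    geo$neckRadius, geo$cytoplasm, spineIds[s])
      .stampCapsule(scene, sg$attach, sg$attach + sg$dir * sg$neckLen,
                    geo$neckRadius, geo$cytoplasm, spineIds[s], onlyBg = TRUE)
      .stampEllipsoid(scene, sg$headC, sg$dir, sg$ra, sg$rr,
                      geo$cytoplasm, spineIds[s], onlyBg = TRUE)
    }
    # repair pass: every spine with in-volume voxels must either touch the
    # stack border (truncation) or be 26-adjacent to its parent dendrite;
    # a neck blocked by an earlier-stamped structure is re-stamped with
    # overwrite priority to restore its own connectivity
    if (length(spineGeo)) {
      parentOf <- denIds[vapply(spineGeo, function(sg) sg$host, integer(1))]
      for (pass in 1:3) {
        okv <- .spinesConnected(scene, spineIds, parentOf)
        broken <- which(!okv)
        if (!length(broken)) break
        for (s in broken) {
          sg <- spineGeo[[s]]
          rootDepth <- min(100, dendrites[[sg$host]]$radius * 0.6)
          .stampCapsule(scene, sg$attach - sg$dir * rootDepth,
                        sg$attach + sg$dir * sg$neckLen,
                        geo$neckRadius, geo$cytoplasm, spineIds[s])
        }
      }
    }
    # all boutons before any plate: a bouton stamped later must never
    # erase a neighbouring junction's densities
    for (m in seq_along(synapses)) {
      sy <- synapses[[m]]
      proj <- sum(abs(sy$normal) * spec@voxelSize)
      cleft <- max(geo$cleft, 1.05 * proj)
      bC <- sy$center + sy$normal * (cleft + geo$preThickness + geo$boutonRadius * 0.8)
      .stampBall(scene, bC, geo$boutonRadius, geo$cytoplasm, NULL)
    }
    for (m in seq_along(synapses)) {
      sy <- synapses[[m]]
      proj <- sum(abs(sy$normal) * spec@voxelSize)
      cleft <- max(geo$cleft, 1.05 * proj)
      # postsynaptic density: inside the postsynaptic element
      .stampPlate(scene, sy$center, sy$normal, sy$plateR, -sy$psd, 0,
                  geo$densityGray, synIds[m], grow = -1)
      # presynaptic density: beyond the cleft
      .stampPlate(scene, sy$center, sy$normal, sy$plateR,
                  cleft, cleft + geo$preThickness,
                  geo$densityGray, synIds[m], grow = 1)
    }

    ## per-object tallies from the rendered labels
    idx <- which(scene$labels != 0L)
    lab <- scene$labels[idx]
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    i <- (idx - 1L) %% nx + 1L
    j <- ((idx - 1L) %/% nx) %% ny + 1L
    k <- (idx - 1L) %/% (nx * ny) + 1L
    maxId <- max(synIds, spineIds, denIds)
    nv <- tabulate(lab, nbins = maxId)
    onBorder <- i == 1L | i == nx | j == 1L | j == ny | k == 1L | k == nz
    nb <- tabulate(lab[onBorder], nbins = maxId)
    cs <- rowsum(cbind((i - 0.5) * spec@voxelSize[1],
                       (j - 0.5) * spec@voxelSize[2],
                       (k - 0.5) * spec@voxelSize[3]), lab)
    cent <- matrix(NA_real_, maxId, 3)
    cent[as.integer(rownames(cs)), ] <- cs / nv[as.integer(rownames(cs))]

    ## noise last
    if (spec@noise[1] > 0 || spec@noise[2] > 0) {
      n <- length(scene$img)
      img <- scene$img + stats::rnorm(n, 0, spec@noise[1])
      if (spec@noise[2] > 0)
        img <- img + stats::rpois(n, spec@noise[2]) - spec@noise[2]
      scene$img <- array(pmin(pmax(img, 0), 255), dim = dims)
    }
  } else {
    nv <- NULL; nb <- NULL; cent <- NULL
  }

  ## ---- assemble ledger
  gTouch <- function(lo, hi) any(lo <= 0) || any(hi >= extentNm)
  rows <- list()
  for (d in seq_len(nDen)) {
    den <- dendrites[[d]]
    lo <- apply(den$path, 2, min) - den$radius
    hi <- apply(den$path, 2, max) + den$radius
    mid <- den$path[ceiling(nrow(den$path) / 2), ]
    rows[[length(rows) + 1L]] <- data.frame(
      id = denIds[d], kind = "dendrite", synapse_type = NA_character_,
      target = NA_character_, parent_dendrite_id = NA_integer_,
      parent_spine_id = NA_integer_, dendrite_is_spiny = den$spiny,
      touches_border = gTouch(lo, hi),
      neck_attached = NA, cx = mid[1], cy = mid[2], cz = mid[3],
      stringsAsFactors = FALSE)
  }
  for (s in seq_along(spineGeo)) {
    sg <- spineGeo[[s]]
    lo <- pmin(sg$attach, sg$headC - sg$ra)
    hi <- pmax(sg$attach, sg$headC + sg$ra)
    rows[[length(rows) + 1L]] <- data.frame(
      id = spineIds[s], kind = "spine", synapse_type = NA_character_,
      target = NA_character_, parent_dendrite_id = denIds[sg$host],
      parent_spine_id = NA_integer_, dendrite_is_spiny = TRUE,
      touches_border = gTouch(lo, hi),
      neck_attached = .insideVolume(sg$attach, extentNm),
      cx = sg$headC[1], cy = sg$headC[2], cz = sg$headC[3],
      stringsAsFactors = FALSE)
  }
  for (m in seq_along(synapses)) {
    sy <- synapses[[m]]
    rows[[length(rows) + 1L]] <- data.frame(
      id = synIds[m], kind = "synapse", synapse_type = sy$type,
      target = sy$target,
      parent_dendrite_id = denIds[sy$dendrite],
      parent_spine_id = if (is.na(sy$spine)) NA_integer_ else spineIds[sy$spine],
      dendrite_is_spiny = dendrites[[sy$dendrite]]$spiny,
      touches_border = FALSE,
      neck_attached = NA, cx = sy$center[1], cy = sy$center[2], cz = sy$center[3],
      stringsAsFactors = FALSE)
  }
  led <- do.call(rbind, rows)
  rownames(led) <- NULL

  if (render) {
    alive <- led$kind == "dendrite" | nv[led$id] > 0L
    # never orphan a live spine's dendrite (dendrites are laid to have
    # in-volume length, so this is belt and braces)
    led <- led[alive, , drop = FALSE]
    present <- led$id
    led$touches_border <- nb[led$id] > 0L
    led$n_voxels <- nv[led$id]
    led$cx <- ifelse(is.na(cent[led$id, 1]), led$cx, cent[led$id, 1])
    led$cy <- ifelse(is.na(cent[led$id, 2]), led$cy, cent[led$id, 2])
    led$cz <- ifelse(is.na(cent[led$id, 3]), led$cz, cent[led$id, 3])
    # drop synapses pointing at dropped spines
    dead <- led$kind == "synapse" & !is.na(led$parent_spine_id) &
      !(led$parent_spine_id %in% present)
    led <- led[!dead, , drop = FALSE]
    scene$labels[!(scene$labels %in% c(0L, led$id))] <- 0L
    truth <- new("GroundTruth", labels = scene$labels, ledger = led,
                 voxelSize = spec@voxelSize)
    vol <- voxelVolume(scene$img, voxelSize = spec@voxelSize)
    list(volume = vol, truth = truth)
  } else {
    led$n_voxels <- NA_integer_
    truth <- new("GroundTruth", labels = array(0L, c(1L, 1L, 1L)), ledger = led,
                 voxelSize = spec@voxelSize)
    list(volume = NULL, truth = truth)
  }
}
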