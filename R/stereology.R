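## Unbiased counting-frame (brick) stereology. The brick has inclusion
## faces at the low ends of x, y, z and exclusion faces at the high ends;
## the exclusion faces carry extended forbidden planes so that, under
## tiling of space by translated bricks, every object is counted exactly
## once. Densities are referred to pre-processing tissue volume through a
## linear-shrinkage correction factor 1/(1-s)^3.

#' Construct an unbiased counting frame
#'
#' Builds the brick by insetting a guard margin from the stack bounds (or
#' from explicit bounds) and computes both the nominal box volume and the
#' shrinkage-corrected volume.
#'
#' @param stackBounds a \linkS4class{VoxelVolume}, or a 2 x 3 matrix of
#'   low/high physical bounds in nm.
#' @param marginNm guard margin in nm (scalar or length-3).
#' @param shrinkage linear tissue shrinkage fraction s in [0, 1); the
#'   volume correction factor is 1/(1-s)^3. Default 0: the factor used in
#'   any given study is a property of its fixation protocol and must be
#'   supplied explicitly.
#' @return A \linkS4class{CountingFrame}.
#' @examples
#' fr <- makeCountingFrame(rbind(c(0, 0, 0), c(1e4, 1e4, 5e3)), marginNm = 1e3)
#' frameVolume(fr)
#' @export
makeCountingFrame <- function(stackBounds, marginNm, shrinkage = 0) {
  if (is(stackBounds, "VoxelVolume")) {
    ext <- dim(voxelData(stackBounds)) * voxelSize(stackBounds)
    stackBounds <- rbind(stackOrigin(stackBounds), stackOrigin(stackBounds) + ext)
  }
  stopifnot(is.matrix(stackBounds), all(dim(stackBounds) == c(2, 3)))
  m <- rep_len(marginNm, 3)
  lo <- stackBounds[1, ] + m
  hi <- stackBounds[2, ] - m
  if (any(hi <= lo)) stop("margin consumes the stack: empty counting frame")
  nominal <- prod(hi - lo) / 1e9
  new("CountingFrame", bounds = rbind(lo, hi), shrinkage = shrinkage,
      nominalVolume = nominal, correctedVolume = nominal / (1 - shrinkage)^3)
}

#' @rdname makeCountingFrame
#' @param frame a CountingFrame.
#' @param corrected return the shrinkage-corrected volume (default) or the
#'   nominal one.
#' @export
frameVolume <- function(frame, corrected = TRUE)
  if (corrected) frame@correctedVolume else frame@nominalVolume

setMethod("show", "CountingFrame", function(object) {
  b <- object@bounds
  cat(sprintf("CountingFrame: [%g, %g] x [%g, %g] x [%g, %g] nm\n",
              b[1, 1], b[2, 1], b[1, 2], b[2, 2], b[1, 3], b[2, 3]))
  cat(sprintf("  nominal %.4g um^3, corrected %.4g um^3 (shrinkage %.3g)\n",
              object@nominalVolume, object@correctedVolume, object@shrinkage))
})

# Coerce the accepted junction representations to a list of nm coordinate
# matrices with per-point half extents.
.junctionPointSets <- function(junctions) {
  if (is(junctions, "JunctionSet")) {
    half <- junctions@voxelSize / 2
    lapply(seq_len(length(junctions)), function(i)
      list(p = junctionCoordsNm(junctions, i), h = half))
  } else if (is.matrix(junctions)) {
    lapply(seq_len(nrow(junctions)), function(i)
      list(p = junctions[i, , drop = FALSE], h = c(0, 0, 0)))
  } else if (is.list(junctions)) {
    lapply(junctions, function(p) {
      if (is.list(p)) p else list(p = p, h = c(0, 0, 0))
    })
  } else stop("unsupported junction representation")
}

#' Count junctions within an unbiased counting frame
#'
#' A junction is counted iff its voxel set intersects the frame box (or
#' its inclusion faces) and touches neither an exclusion face nor its
#' extended forbidden plane. The decision uses the whole voxel set, never
#' the centroid: junctions are extended plates and a centroid rule
#' undercounts obliquely cut ones. Point-like objects may be supplied as
#' an n x 3 matrix of nm coordinates (one row per object).
#'
#' @param junctions a \linkS4class{JunctionSet}, an n x 3 matrix of point
#'   objects, or a list of nm coordinate matrices.
#' @param frame a \linkS4class{CountingFrame}.
#' @return Integer count.
#' @export
countInFrame <- function(junctions, frame) {
  sets <- .junctionPointSets(junctions)
  lo <- frame@bounds[1, ]; hi <- frame@bounds[2, ]
  counted <- vapply(sets, function(s) {
    p <- s$p; h <- s$h
    pl <- sweep(p, 2, h)          # voxel box low corner
    ph <- sweep(p, 2, h, "+")     # voxel box high corner
    inBox <- any(ph[, 1] >= lo[1] & pl[, 1] <= hi[1] &
                 ph[, 2] >= lo[2] & pl[, 2] <= hi[2] &
                 ph[, 3] >= lo[3] & pl[, 3] <= hi[3])
    if (!inBox) return(FALSE)
    # extended forbidden planes at the three high faces: the plane at
    # x = hi_x spans y >= lo_y, z >= lo_z (and cyclically)
    touchX <- any(pl[, 1] <= hi[1] & ph[, 1] >= hi[1] &
                  ph[, 2] >= lo[2] & ph[, 3] >= lo[3])
    touchY <- any(pl[, 2] <= hi[2] & ph[, 2] >= hi[2] &
                  ph[, 1] >= lo[1] & ph[, 3] >= lo[3])
    touchZ <- any(pl[, 3] <= hi[3] & ph[, 3] >= hi[3] &
                  ph[, 1] >= lo[1] & ph[, 2] >= lo[2])
    !(touchX || touchY || touchZ)
  }, logical(1))
  sum(counted)
}

#' Synapse density from a frame count
#'
#' @param count number of junctions counted in the frame.
#' @param frame a \linkS4class{CountingFrame}.
#' @return Synapses per um^3, referred to shrinkage-corrected volume.
#' @export
synapseDensity <- function(count, frame) {
  stopifnot(count >= 0)
  count / frameVolume(frame)
}
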