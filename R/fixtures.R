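## Small deterministic reference fixtures: hand-constructed scenes used
## throughout the test-suite as ground truth with known answers. All are
## 96 x 96 x 32 voxels at 8 x 8 x 20 nm (768 x 768 x 640 nm), noise-free.

.tallyLabels <- function(labels, vx) {
  idx <- which(labels != 0L)
  d <- dim(labels); nx <- d[1]; ny <- d[2]; nz <- d[3]
  i <- (idx - 1L) %% nx + 1L
  j <- ((idx - 1L) %/% nx) %% ny + 1L
  k <- (idx - 1L) %/% (nx * ny) + 1L
  lab <- labels[idx]
  maxId <- if (length(lab)) max(lab) else 0L
  nv <- tabulate(lab, nbins = maxId)
  onBorder <- i == 1L | i == nx | j == 1L | j == ny | k == 1L | k == nz
  nb <- tabulate(lab[onBorder], nbins = maxId)
  list(nv = nv, nb = nb)
}

.ledgerRow <- function(id, kind, type = NA_character_, target = NA_character_,
                       den = NA_integer_, spine = NA_integer_,
                       spiny = NA, border = FALSE, attached = NA,
                       c0 = c(NA_real_, NA_real_, NA_real_)) {
  data.frame(id = id, kind = kind, synapse_type = type, target = target,
             parent_dendrite_id = den, parent_spine_id = spine,
             dendrite_is_spiny = spiny, touches_border = border,
             neck_attached = attached, cx = c0[1], cy = c0[2], cz = c0[3],
             n_voxels = NA_integer_, stringsAsFactors = FALSE)
}

.newScene <- function(dims = c(96L, 96L, 32L), vx = c(8, 8, 20), bg = 200) {
  scene <- new.env(parent = emptyenv())
  scene$dims <- as.integer(dims)
  scene$vx <- vx
  scene$img <- array(bg, dim = dims)
  scene$labels <- array(0L, dim = dims)
  scene
}

.stampSynapsePair <- function(scene, center, normal, psd, label,
                              plateR = 140, pre = 20, cleftNm = 20,
                              gray = 40, bouton = TRUE) {
  proj <- sum(abs(normal) * scene$vx)
  cleft <- max(cleftNm, 1.05 * proj)
  if (bouton)
    .stampBall(scene, center + normal * (cleft + pre + 150), 180, 190, NULL)
  .stampPlate(scene, center, normal, plateR, -psd, 0, gray, label, grow = -1)
  .stampPlate(scene, center, normal, plateR, cleft, cleft + pre, gray, label,
              grow = 1)
}

.finishFixture <- function(scene, rows) {
  led <- do.call(rbind, rows)
  tl <- .tallyLabels(scene$labels, scene$vx)
  led$touches_border <- tl$nb[led$id] > 0L
  led$n_voxels <- tl$nv[led$id]
  truth <- new("GroundTruth", labels = scene$labels, ledger = led,
               voxelSize = scene$vx)
  list(volume = voxelVolume(scene$img, voxelSize = scene$vx), truth = truth)
}

#' Deterministic reference fixtures
#'
#' Small hand-constructed scenes with exhaustively known ground truth:
#' \describe{
#'   \item{two_blobs}{two disjoint dark ellipsoids on a bright background.}
#'   \item{single_AS_on_head}{one dendrite, one spine, one asymmetric
#'     junction on the spine head.}
#'   \item{single_SS_on_shaft}{one spine-free dendrite with a symmetric
#'     junction on its shaft.}
#'   \item{truncated_spine}{a spine whose neck enters through the stack
#'     floor; its parent dendrite cannot be reached inside the volume.}
#'   \item{multi_synapse_spine}{one spine carrying one AS and one SS.}
#' }
#' All fixtures are 96 x 96 x 32 voxels at 8 x 8 x 20 nm and noise-free.
#'
#' @param name fixture id.
#' @return A list with `volume` (\linkS4class{VoxelVolume}) and `truth`
#'   (\linkS4class{GroundTruth}).
#' @examples
#' fx <- renderReferenceFixture("single_AS_on_head")
#' ledger(fx$truth)
#' @export
renderReferenceFixture <- function(name = c("two_blobs", "single_AS_on_head",
                                            "single_SS_on_shaft",
                                            "truncated_spine",
                                            "multi_synapse_spine")) {
  name <- match.arg(name)
  switch(name,
    two_blobs = {
      scene <- .newScene()
      .stampEllipsoid(scene, c(250, 250, 320), c(1, 0, 0), 120, 90, 40, 1L)
      .stampEllipsoid(scene, c(550, 500, 320), c(0, 0, 1), 100, 110, 40, 2L)
      rows <- list(
        .ledgerRow(1L, "synapse", "AS", "shaft", c0 = c(250, 250, 320)),
        .ledgerRow(2L, "synapse", "AS", "shaft", c0 = c(550, 500, 320)))
      .finishFixture(scene, rows)
    },
    single_AS_on_head = {
      scene <- .newScene()
      .stampCapsule(scene, c(-100, 200, 320), c(900, 200, 320), 120, 190, 1L)
      attach <- c(384, 320, 320)
      .stampCapsule(scene, attach - c(0, 40, 0), attach + c(0, 150, 0), 60, 190, 2L)
      headC <- c(384, 582, 320)
      .stampEllipsoid(scene, headC, c(0, 1, 0), 140, 120, 190, 2L)
      synC <- headC + c(120, 0, 0)
      .stampSynapsePair(scene, synC, c(1, 0, 0), 50, 3L)
      rows <- list(
        .ledgerRow(1L, "dendrite", spiny = TRUE, c0 = c(384, 200, 320)),
        .ledgerRow(2L, "spine", den = 1L, spiny = TRUE, attached = TRUE, c0 = headC),
        .ledgerRow(3L, "synapse", "AS", "head", den = 1L, spine = 2L,
                   spiny = TRUE, c0 = synC))
      .finishFixture(scene, rows)
    },
    single_SS_on_shaft = {
      scene <- .newScene()
      .stampCapsule(scene, c(-100, 384, 320), c(900, 384, 320), 150, 190, 1L)
      synC <- c(384, 534, 320)
      .stampSynapsePair(scene, synC, c(0, 1, 0), 20, 2L)
      rows <- list(
        .ledgerRow(1L, "dendrite", spiny = FALSE, c0 = c(384, 384, 320)),
        .ledgerRow(2L, "synapse", "SS", "shaft", den = 1L, spiny = FALSE,
                   c0 = synC))
      .finishFixture(scene, rows)
    },
    truncated_spine = {
      scene <- .newScene()
      # dendrite enters the volume at low x, then dives under the stack
      # floor where the spine attaches
      p <- rbind(c(-100, 384, 150), c(250, 384, 100), c(420, 384, -250),
                 c(900, 384, -250))
      for (s in seq_len(nrow(p) - 1L))
        .stampCapsule(scene, p[s, ], p[s + 1L, ], 120, 190, 1L)
      attach <- c(600, 384, -130)
      .stampCapsule(scene, attach, attach + c(0, 0, 300), 60, 190, 2L)
      headC <- c(600, 384, 282)
      .stampEllipsoid(scene, headC, c(0, 0, 1), 140, 120, 190, 2L)
      synC <- headC + c(120, 0, 0)
      .stampSynapsePair(scene, synC, c(1, 0, 0), 50, 3L)
      rows <- list(
        .ledgerRow(1L, "dendrite", spiny = TRUE, c0 = c(250, 384, 100)),
        .ledgerRow(2L, "spine", den = 1L, spiny = TRUE, attached = FALSE,
                   c0 = headC),
        .ledgerRow(3L, "synapse", "AS", "head", den = 1L, spine = 2L,
                   spiny = TRUE, c0 = synC))
      .finishFixture(scene, rows)
    },
    multi_synapse_spine = {
      scene <- .newScene()
      .stampCapsule(scene, c(-100, 200, 320), c(900, 200, 320), 120, 190, 1L)
      attach <- c(384, 320, 320)
      .stampCapsule(scene, attach - c(0, 40, 0), attach + c(0, 150, 0), 60, 190, 2L)
      headC <- c(384, 582, 320)
      .stampEllipsoid(scene, headC, c(0, 1, 0), 140, 120, 190, 2L)
      .stampSynapsePair(scene, headC + c(120, 0, 0), c(1, 0, 0), 50, 3L)
      .stampSynapsePair(scene, headC - c(120, 0, 0), c(-1, 0, 0), 20, 4L)
      rows <- list(
        .ledgerRow(1L, "dendrite", spiny = TRUE, c0 = c(384, 200, 320)),
        .ledgerRow(2L, "spine", den = 1L, spiny = TRUE, attached = TRUE,
                   c0 = headC),
        .ledgerRow(3L, "synapse", "AS", "head", den = 1L, spine = 2L,
                   spiny = TRUE, c0 = headC + c(120, 0, 0)),
        .ledgerRow(4L, "synapse", "SS", "head", den = 1L, spine = 2L,
                   spiny = TRUE, c0 = headC - c(120, 0, 0)))
      .finishFixture(scene, rows)
    })
}
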