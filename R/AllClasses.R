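#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib synapseCensus, .registration = TRUE
NULL

#' VoxelVolume: a 3D grayscale image stack with anisotropic voxel metadata
#'
#' The raw imaging substrate of the pipeline: a 3D array of gray values
#' (FIB/SEM convention: bright background, dark electron-dense structures)
#' together with the physical voxel dimensions in nanometres and the stack
#' origin. FIB/SEM stacks are strongly anisotropic (a few nm per pixel in
#' xy, tens of nm of milling depth per section in z), so every geometric
#' operation in the package consumes `voxelSize` rather than assuming cubic
#' voxels.
#'
#' @slot data 3D numeric array of gray values (stored as numeric; 8-bit
#'   stacks use the range 0-255).
#' @slot voxelSize numeric length-3, voxel edge lengths in nm (x, y, z);
#'   z is the section thickness.
#' @slot origin numeric length-3, physical position (nm) of the voxel
#'   with index (1,1,1); physical centre of voxel (i,j,k) is
#'   `origin + (index - 0.5) * voxelSize`.
#' @export
setClass("VoxelVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = c(4, 4, 20), origin = c(0, 0, 0))
)

setValidity("VoxelVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 strictly positive values (nm)")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (length(object@data) == 0L) msg <- c(msg, "data must be non-empty")
  if (is.null(msg)) TRUE else msg
})

#' GroundTruth: label volume plus object ledger for a synthetic stack
#'
#' What the synthetic generator emits alongside the image, and what the
#' segmentation and annotation stages are scored against. The label volume
#' holds one integer object id per voxel (0 = background / unlabelled
#' material such as axonal boutons); the ledger is one row per object.
#'
#' @slot labels integer 3D array, same shape as the image.
#' @slot ledger data.frame with columns `id`, `kind` (dendrite | spine |
#'   synapse), `synapse_type` (AS | SS | NA), `target` (head | neck | shaft |
#'   NA), `parent_dendrite_id`, `parent_spine_id`, `dendrite_is_spiny`,
#'   `touches_border`, plus centroid columns `cx`, `cy`, `cz` (nm).
#' @slot voxelSize numeric length-3, nm.
#' @export
setClass("GroundTruth",
  representation(labels = "array", ledger = "data.frame", voxelSize = "numeric")
)

setValidity("GroundTruth", function(object) {
  msg <- NULL
  need <- c("id", "kind", "synapse_type", "target", "parent_dendrite_id",
            "parent_spine_id", "dendrite_is_spiny", "touches_border")
  if (!all(need %in% names(object@ledger)))
    msg <- c(msg, paste("ledger lacks columns:",
                        paste(setdiff(need, names(object@ledger)), collapse = ", ")))
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3D array")
  if (nrow(object@ledger) && anyDuplicated(object@ledger$id))
    msg <- c(msg, "ledger ids must be unique")
  led <- object@ledger
  if (nrow(led)) {
    sp <- led[led$kind == "spine", ]
    if (any(!sp$parent_dendrite_id %in% led$id[led$kind == "dendrite"]))
      msg <- c(msg, "every spine must have a parent dendrite in the ledger")
    sy <- led[led$kind == "synapse", ]
    if (any(is.na(sy$target)))
      msg <- c(msg, "every synapse must have exactly one target")
  }
  if (is.null(msg)) TRUE else msg
})

#' NeuropilSpec: parameters of the synthetic neuropil generator
#'
#' Houses the study conditions the generator emulates: stack geometry and
#' resolution, the expected volumetric synapse intensity, the AS/SS mixture,
#' targeting fractions (spines vs shafts, head vs neck), the single/multiple
#' synapse-per-spine mixture, the spiny share of shaft targets, shrinkage
#' and noise. Defaults are the layer-averaged empirical values of the
#' bundled juvenile rat somatosensory-cortex census (see
#' \code{\link{referenceCounts}}).
#'
#' @slot volumeExtent numeric length-3, stack extent in micrometres.
#' @slot voxelSize numeric length-3, nm; xy typically 3.7-4.5 nm, z 20 nm.
#' @slot synapseIntensity expected synapses per cubic micrometre.
#' @slot asFraction proportion of asymmetric synapses among all synapses.
#' @slot spineTargetFractionAS,spineTargetFractionSS proportion of AS (SS)
#'   synapses whose target is a spine rather than a shaft.
#' @slot headFraction among axospinous synapses, proportion on the head.
#' @slot multiSynapseFraction proportion of innervated spines carrying more
#'   than one synapse.
#' @slot multiMix named numeric, categorical weights over the multi-synapse
#'   combinations (two_AS, one_AS_one_SS, two_AS_one_SS, three_AS, two_SS,
#'   three_SS, one_AS_two_SS); must sum to 1.
#' @slot singleASFraction among single-synapse spines, proportion whose
#'   synapse is AS.
#' @slot spinyShaftFraction proportion of shaft-targeting synapses whose
#'   dendrite is spiny.
#' @slot shrinkage linear tissue shrinkage fraction s in [0,1); densities
#'   are referred to pre-processing volume via 1/(1-s)^3.
#' @slot noise numeric length-2: Gaussian sd and Poisson dark-current mean,
#'   in gray levels.
#' @slot geometry named list of rendering parameters (gray levels, dendrite
#'   diameter range, spine and plate dimensions, PSD thickness ranges);
#'   see \code{\link{neuropilSpec}}.
#' @slot rngSeed integer seed.
#' @export
setClass("NeuropilSpec",
  representation(
    volumeExtent = "numeric", voxelSize = "numeric",
    synapseIntensity = "numeric", asFraction = "numeric",
    spineTargetFractionAS = "numeric", spineTargetFractionSS = "numeric",
    headFraction = "numeric", multiSynapseFraction = "numeric",
    multiMix = "numeric", singleASFraction = "numeric",
    spinyShaftFraction = "numeric", shrinkage = "numeric",
    noise = "numeric", geometry = "list", rngSeed = "integer"
  )
)

setValidity("NeuropilSpec", function(object) {
  msg <- NULL
  fr <- c(object@asFraction, object@spineTargetFractionAS,
          object@spineTargetFractionSS, object@headFraction,
          object@multiSynapseFraction, object@singleASFraction,
          object@spinyShaftFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must lie in [0, 1]")
  if (any(object@volumeExtent <= 0) || any(object@voxelSize <= 0))
    msg <- c(msg, "volumeExtent and voxelSize must be strictly positive")
  if (abs(sum(object@multiMix) - 1) > 1e-8)
    msg <- c(msg, "multiMix weights must sum to 1")
  if (object@shrinkage < 0 || object@shrinkage >= 1)
    msg <- c(msg, "shrinkage must lie in [0, 1)")
  if (object@synapseIntensity < 0) msg <- c(msg, "synapseIntensity must be >= 0")
  if (length(object@noise) != 2L || any(object@noise < 0))
    msg <- c(msg, "noise must be c(gaussian_sd, dark_current), both >= 0")
  if (is.null(msg)) TRUE else msg
})

#' JunctionSet: segmented synaptic junctions of one stack
#'
#' One row of `info` per extracted 3D junction (connected component of the
#' thresholded dark mask), with the voxel coordinates of each junction kept
#' as an integer matrix in the parallel `voxels` list. Junction geometry is
#' physical: centroids in nm, volumes in nm^3, postsynaptic-density
#' thickness in nm.
#'
#' @slot info data.frame with columns `id`, `cx`, `cy`, `cz` (centroid, nm),
#'   `n_voxels`, `volume_nm3`, `psd_thickness_nm`, `type`
#'   (AS | SS | unclassified).
#' @slot voxels list of n x 3 integer matrices of voxel indices (1-based).
#' @slot voxelSize numeric length-3, nm.
#' @export
setClass("JunctionSet",
  representation(info = "data.frame", voxels = "list", voxelSize = "numeric")
)

setValidity("JunctionSet", function(object) {
  msg <- NULL
  if (nrow(object@info) != length(object@voxels))
    msg <- c(msg, "info rows and voxels list must have equal length")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values")
  if (nrow(object@info)) {
    vv <- prod(object@voxelSize)
    nv <- vapply(object@voxels, nrow, integer(1))
    if (any(abs(object@info$volume_nm3 - nv * vv) > 1e-6 * vv))
      msg <- c(msg, "volume_nm3 must equal n_voxels * prod(voxelSize)")
    if (any(object@info$psd_thickness_nm < 0, na.rm = TRUE))
      msg <- c(msg, "psd_thickness_nm must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' CountingFrame: an unbiased 3D counting brick
#'
#' An axis-aligned box strictly inside the stack, with inclusion faces at
#' the low ends of x, y and z and exclusion faces (plus their extended
#' forbidden planes) at the high ends. A junction is counted if it
#' intersects the brick and touches no exclusion surface, which under
#' tiling counts every object exactly once regardless of its size or
#' position. Volumes carry a tissue-shrinkage correction so densities refer
#' to pre-processing tissue.
#'
#' @slot bounds 2 x 3 numeric matrix (rows: low, high; columns x, y, z), nm.
#' @slot shrinkage linear shrinkage fraction s in [0,1).
#' @slot nominalVolume nominal box volume, um^3.
#' @slot correctedVolume nominal volume times 1/(1-s)^3, um^3.
#' @export
setClass("CountingFrame",
  representation(bounds = "matrix", shrinkage = "numeric",
                 nominalVolume = "numeric", correctedVolume = "numeric")
)

setValidity("CountingFrame", function(object) {
  msg <- NULL
  b <- object@bounds
  if (!all(dim(b) == c(2, 3))) msg <- c(msg, "bounds must be a 2x3 matrix")
  else if (any(b[2, ] <= b[1, ])) msg <- c(msg, "frame box must be non-empty")
  s <- object@shrinkage
  if (s < 0 || s >= 1) msg <- c(msg, "shrinkage must lie in [0, 1)")
  if (!is.null(dim(b)) && all(dim(b) == c(2, 3))) {
    nom <- prod(b[2, ] - b[1, ]) / 1e9
    if (abs(object@nominalVolume - nom) > 1e-6 * max(nom, 1))
      msg <- c(msg, "nominalVolume must equal the box volume")
    if (abs(object@correctedVolume - nom / (1 - s)^3) > 1e-6 * max(nom, 1))
      msg <- c(msg, "correctedVolume must equal nominal / (1-s)^3")
  }
  if (is.null(msg)) TRUE else msg
})

#' LayerCountTable: per-layer synapse counts by type and target
#'
#' Counts of the six synapse-by-target categories (AS and SS on spine
#' heads, spine necks and dendritic shafts) for cortical layers I-VI, the
#' input shape of all percentage tables and contingency analyses. Optional
#' per-layer AS/SS densities (synapses per um^3) feed the density table;
#' optional spine-profile tallies feed the single/multiple-synapse table.
#'
#' @slot counts 6 x 6 numeric matrix; rows AS_head, AS_neck, AS_shaft,
#'   SS_head, SS_neck, SS_shaft; columns layers I-VI.
#' @slot densities numeric matrix (2 x 6, rows AS, SS) of per-layer synapse
#'   densities per um^3, or a 0x0 matrix when unavailable.
#' @slot spineProfiles named numeric vector of spine-profile counts in the
#'   categories of \code{\link{profileSpines}}, or empty.
#' @export
setClass("LayerCountTable",
  representation(counts = "matrix", densities = "matrix",
                 spineProfiles = "numeric")
)

.categoryNames <- c("AS_head", "AS_neck", "AS_shaft", "SS_head", "SS_neck", "SS_shaft")
.layerNames <- c("I", "II", "III", "IV", "V", "VI")

setValidity("LayerCountTable", function(object) {
  msg <- NULL
  cm <- object@counts
  if (!all(dim(cm) == c(6, 6)))
    msg <- c(msg, "counts must be 6 categories x 6 layers")
  else {
    if (!identical(rownames(cm), .categoryNames))
      msg <- c(msg, paste("count rows must be", paste(.categoryNames, collapse = ", ")))
    if (any(cm < 0)) msg <- c(msg, "all counts must be >= 0")
  }
  if (length(object@densities) && !identical(rownames(object@densities), c("AS", "SS")))
    msg <- c(msg, "densities must have rows AS, SS")
  if (is.null(msg)) TRUE else msg
})
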