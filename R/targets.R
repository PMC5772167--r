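## Postsynaptic-target annotation. The postsynaptic object of each synapse
## (spine or shaft) comes from the annotation ledger; spine-targeting
## synapses are only accepted as identified when the spine can be traced
## through the label volume to a parent dendrite. A spine clipped by the
## stack border before a parent is reached is "truncated": its synapse is
## excluded from target-proportion tables but still counts toward density.
## A dendrite is "spiny" iff at least one spine attaches to it within the
## analyzed volume; a spine-free segment is "not determined", never
## "aspiny" (absence of spines in the sampled volume proves nothing).

# per-object voxel index cache: list of n x 3 integer matrices keyed by id
.objectVoxels <- function(truth) {
  lab <- labelVolume(truth)
  idx <- which(lab != 0L)
  if (!length(idx)) return(list())
  d <- dim(lab); nx <- d[1]; ny <- d[2]
  i <- (idx - 1L) %% nx + 1L
  j <- ((idx - 1L) %/% nx) %% ny + 1L
  k <- (idx - 1L) %/% (nx * ny) + 1L
  split(data.frame(i = i, j = j, k = k), lab[idx])
}

.offsets26 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
})

# ids of objects whose voxels touch the 26-neighbourhood of `vox`
.adjacentLabels <- function(vox, lab) {
  d <- dim(lab)
  hits <- integer(0)
  for (r in seq_len(nrow(.offsets26))) {
    i <- vox$i + .offsets26$di[r]
    j <- vox$j + .offsets26$dj[r]
    k <- vox$k + .offsets26$dk[r]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
    if (!any(ok)) next
    hits <- c(hits, lab[cbind(i[ok], j[ok], k[ok])])
  }
  hits[hits != 0L]
}

#' Trace a spine to its parent dendrite
#'
#' Searches the 26-neighbourhood of the spine's in-volume voxels for
#' dendrite voxels. When the annotation designates a parent (`expected`),
#' the trace verifies that this parent is reached through the labels --
#' annotation is bookkeeping, and the trace checks its physical
#' continuity. Without a designated parent the adjacent dendrite with the
#' largest contact is returned: a spine clipped at the stack border can
#' incidentally touch a passing dendrite, so the designated-parent form
#' is the reliable one whenever a ledger is available. If no (expected)
#' parent is reached and the spine touches a stack face, the spine is
#' truncated -- the parent lies outside the imaged volume -- and
#' `"truncated"` is returned.
#'
#' @param objectId id of the spine (or shaft object) in the ledger.
#' @param truth a \linkS4class{GroundTruth} (or equivalent annotation
#'   volume with ledger).
#' @param expected id of the annotated parent dendrite to verify, or NULL
#'   to discover the parent by largest label contact.
#' @param cache optional precomputed object-voxel cache (internal use).
#' @return Parent dendrite id (integer) or the string `"truncated"`.
#' @export
traceToParent <- function(objectId, truth, expected = NULL, cache = NULL) {
  led <- ledger(truth)
  row <- led[led$id == objectId, , drop = FALSE]
  if (!nrow(row)) stop("unknown object id: ", objectId)
  if (row$kind == "dendrite") return(as.integer(objectId))
  if (is.null(cache)) cache <- .objectVoxels(truth)
  vox <- cache[[as.character(objectId)]]
  lab <- labelVolume(truth)
  denIds <- led$id[led$kind == "dendrite"]
  if (!is.null(vox) && nrow(vox)) {
    hits <- .adjacentLabels(vox, lab)
    hits <- hits[hits %in% denIds]
    if (!is.null(expected)) {
      if (expected %in% hits) return(as.integer(expected))
    } else if (length(hits)) {
      tab <- table(hits)
      return(as.integer(names(tab)[which.max(tab)]))
    }
    d <- dim(lab)
    onBorder <- any(vox$i == 1L | vox$i == d[1] | vox$j == 1L | vox$j == d[2] |
                    vox$k == 1L | vox$k == d[3])
    if (onBorder) return("truncated")
  } else if (isTRUE(row$touches_border)) {
    return("truncated")
  }
  stop("annotation integrity error: object ", objectId,
       " reaches no dendrite and does not touch the stack border")
}

#' Classify a dendrite as spiny or not-determined
#'
#' Spiny iff at least one ledger spine attaches to the dendrite within the
#' analyzed volume (i.e. traces back to it through the labels). A
#' dendrite without in-volume spines is `"not_determined"`: it may belong
#' to an aspiny interneuron or simply carry no spines in the sampled
#' volume, and the two cannot be distinguished.
#'
#' @inheritParams traceToParent
#' @param dendriteId dendrite id.
#' @return `"spiny"` or `"not_determined"`.
#' @export
classifyDendrite <- function(dendriteId, truth, cache = NULL) {
  led <- ledger(truth)
  if (!dendriteId %in% led$id[led$kind == "dendrite"])
    stop("unknown dendrite id: ", dendriteId)
  if (is.null(cache)) cache <- .objectVoxels(truth)
  spines <- led$id[led$kind == "spine" &
                   led$parent_dendrite_id == dendriteId &
                   led$id %in% names(cache)]
  for (s in spines) {
    tr <- tryCatch(traceToParent(s, truth,
                                 expected = dendriteId, cache = cache),
                   error = function(e) NA)
    if (identical(tr, as.integer(dendriteId))) return("spiny")
  }
  "not_determined"
}

#' Assign each synapse its postsynaptic target
#'
#' The postsynaptic object of each ledger synapse is taken from the
#' annotation (generator ledger or an external annotation volume); spine
#' targets are then validated by tracing the spine to a parent dendrite
#' through the labels. Synapses whose postsynaptic element cannot be
#' traced and touches the stack border are `truncated` with both parents
#' null. The result is deterministic bookkeeping, not inference.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @return A data.frame with one row per synapse: `synapse_id`,
#'   `synapse_type`, `target` (head | neck | shaft | truncated),
#'   `parent_spine_id`, `parent_dendrite_id`, `dendrite_class`
#'   (spiny | not_determined | NA when truncated).
#' @export
assignTargets <- function(truth) {
  led <- ledger(truth)
  syn <- led[led$kind == "synapse", , drop = FALSE]
  cache <- .objectVoxels(truth)
  rendered <- length(cache) > 0L
  dendClassCache <- new.env(parent = emptyenv())
  dendClass <- function(d) {
    key <- as.character(d)
    if (is.null(dendClassCache[[key]]))
      dendClassCache[[key]] <- if (rendered) classifyDendrite(d, truth, cache)
        else if (any(led$kind == "spine" & led$parent_dendrite_id == d &
                     led$neck_attached)) "spiny" else "not_determined"
    dendClassCache[[key]]
  }

  out <- lapply(seq_len(nrow(syn)), function(r) {
    s <- syn[r, ]
    if (!is.na(s$parent_spine_id)) {
      tr <- if (rendered)
          traceToParent(s$parent_spine_id, truth,
                        expected = s$parent_dendrite_id, cache = cache)
        else if (isTRUE(led$neck_attached[led$id == s$parent_spine_id]))
          as.integer(s$parent_dendrite_id) else "truncated"
      if (identical(tr, "truncated"))
        data.frame(synapse_id = s$id, synapse_type = s$synapse_type,
                   target = "truncated", parent_spine_id = NA_integer_,
                   parent_dendrite_id = NA_integer_,
                   dendrite_class = NA_character_, stringsAsFactors = FALSE)
      else
        data.frame(synapse_id = s$id, synapse_type = s$synapse_type,
                   target = s$target, parent_spine_id = s$parent_spine_id,
                   parent_dendrite_id = tr,
                   dendrite_class = dendClass(tr), stringsAsFactors = FALSE)
    } else {
      data.frame(synapse_id = s$id, synapse_type = s$synapse_type,
                 target = "shaft", parent_spine_id = NA_integer_,
                 parent_dendrite_id = s$parent_dendrite_id,
                 dendrite_class = dendClass(s$parent_dendrite_id),
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(synapse_id = integer(0), synapse_type = character(0),
                      target = character(0), parent_spine_id = integer(0),
                      parent_dendrite_id = integer(0),
                      dendrite_class = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

.profileCategories <- c("one_AS", "one_SS", "two_AS", "one_AS_one_SS",
                        "two_AS_one_SS", "three_AS", "two_SS", "three_SS",
                        "one_AS_two_SS", "overflow")

.profileCategory <- function(nAS, nSS) {
  n <- nAS + nSS
  if (n > 3L) return("overflow")
  if (n == 1L) return(if (nAS == 1L) "one_AS" else "one_SS")
  key <- paste(nAS, nSS)
  switch(key,
         "2 0" = "two_AS", "1 1" = "one_AS_one_SS", "0 2" = "two_SS",
         "3 0" = "three_AS", "2 1" = "two_AS_one_SS", "1 2" = "one_AS_two_SS",
         "0 3" = "three_SS")
}

#' Tabulate single- and multi-synapse spines
#'
#' One profile per spine receiving at least one identified synapse, with
#' the AS/SS combination category (one AS; one SS; two AS; one AS + one
#' SS; two AS + one SS; three AS; two SS; three SS; one AS + two SS).
#' Spines with more than three synapses fall into an `overflow` category
#' with a warning -- none occur under the bundled empirical mixture.
#'
#' @param assignments output of \code{\link{assignTargets}} (or any
#'   data.frame with `parent_spine_id`, `synapse_type`, `target`).
#' @return A data.frame with one row per spine: `spine_id`, `n_AS`,
#'   `n_SS`, `n_head`, `n_neck`, `category`, `multiple`.
#' @export
profileSpines <- function(assignments) {
  ax <- assignments[!is.na(assignments$parent_spine_id) &
                    assignments$target %in% c("head", "neck"), , drop = FALSE]
  if (!nrow(ax))
    return(data.frame(spine_id = integer(0), n_AS = integer(0),
                      n_SS = integer(0), n_head = integer(0),
                      n_neck = integer(0), category = character(0),
                      multiple = logical(0), stringsAsFactors = FALSE))
  sp <- split(ax, ax$parent_spine_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    nAS <- sum(g$synapse_type == "AS"); nSS <- sum(g$synapse_type == "SS")
    data.frame(spine_id = g$parent_spine_id[1], n_AS = nAS, n_SS = nSS,
               n_head = sum(g$target == "head"), n_neck = sum(g$target == "neck"),
               category = .profileCategory(nAS, nSS),
               multiple = nAS + nSS > 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$category == "overflow"))
    warning("spines with more than three synapses present (overflow category)")
  out
}

#' @rdname profileSpines
#' @param profiles output of `profileSpines`.
#' @return `spineProfileCounts` returns a named integer vector over the
#'   profile categories.
#' @export
spineProfileCounts <- function(profiles) {
  counts <- table(factor(profiles$category, levels = .profileCategories))
  stats::setNames(as.integer(counts), .profileCategories)
}
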