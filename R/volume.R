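#' Construct a VoxelVolume
#'
#' @param data 3D numeric array of gray values.
#' @param voxelSize voxel edge lengths in nm (x, y, z).
#' @param origin physical position of voxel (1,1,1), nm.
#' @return A \linkS4class{VoxelVolume}.
#' @examples
#' v <- voxelVolume(array(200, c(8, 8, 4)), voxelSize = c(4, 4, 20))
#' dim(voxelData(v))
#' @export
voxelVolume <- function(data, voxelSize = c(4, 4, 20), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("VoxelVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' @rdname voxelVolume
#' @param x a VoxelVolume (or, for `voxelSize`, any object carrying voxel
#'   metadata: VoxelVolume, GroundTruth or JunctionSet).
#' @export
voxelData <- function(x) x@data

#' @rdname voxelVolume
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname voxelVolume
#' @export
stackOrigin <- function(x) x@origin

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, voxel %.4g x %.4g x %.4g nm\n",
              d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  extent %.3g x %.3g x %.3g um, gray range [%g, %g]\n",
              d[1] * object@voxelSize[1] / 1e3, d[2] * object@voxelSize[2] / 1e3,
              d[3] * object@voxelSize[3] / 1e3,
              min(object@data), max(object@data)))
})

setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@ledger$kind)
  cat("GroundTruth:", paste(sprintf("%d %ss", as.integer(tab), names(tab)),
                            collapse = ", "), "\n")
})

#' @rdname groundTruthAccessors
#' @title Ground-truth accessors
#' @description Accessors for \linkS4class{GroundTruth}: the integer label
#'   volume and the object ledger.
#' @param x a GroundTruth.
#' @export
labelVolume <- function(x) x@labels

#' @rdname groundTruthAccessors
#' @export
ledger <- function(x) x@ledger

#' Reslice a stack through an orthogonal plane
#'
#' Permutes the array axes (and voxel-size metadata consistently) so that
#' the chosen axis becomes the leading one. Junctions cut obliquely or "en
#' face" are much easier to inspect after reslicing because the plane of
#' section changes. Applying `resliceInverse` of the same axis restores the
#' original stack bit for bit.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param axis "x", "y" or "z": the axis brought to the front.
#' @return A VoxelVolume with permuted axes and metadata.
#' @export
reslice <- function(volume, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  perm <- switch(axis, x = c(1L, 2L, 3L), y = c(2L, 1L, 3L), z = c(3L, 1L, 2L))
  voxelVolume(aperm(volume@data, perm),
              voxelSize = volume@voxelSize[perm],
              origin = volume@origin[perm])
}

#' @rdname reslice
#' @export
resliceInverse <- function(volume, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  perm <- switch(axis, x = c(1L, 2L, 3L), y = c(2L, 1L, 3L), z = c(3L, 1L, 2L))
  inv <- order(perm)
  voxelVolume(aperm(volume@data, inv),
              voxelSize = volume@voxelSize[inv],
              origin = volume@origin[inv])
}

#' Write / read a stack as multipage TIFF with JSON metadata
#'
#' One TIFF page per z-section plus a `<name>.json` sidecar holding voxel
#' size and origin; the sidecar is the authoritative source of physical
#' metadata on read. Gray values are scaled from [0, 255] to [0, 1] for
#' 8-bit TIFF storage and rescaled on read.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param path output TIFF path (the sidecar replaces the extension
#'   with `.json`).
#' @return `writeStack` returns `path` invisibly; `readStack` returns a
#'   VoxelVolume.
#' @export
writeStack <- function(volume, path) {
  d <- voxelData(volume)
  pages <- lapply(seq_len(dim(d)[3]),
                  function(k) t(pmin(pmax(d[, , k], 0), 255)) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(voxel_size_nm = voxelSize(volume), origin_nm = stackOrigin(volume),
               dim = dim(d))
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sub("\\.[^.]*$", ".json", path),
                              simplifyVector = TRUE)
  arr <- array(0, dim = meta$dim)
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]]) * 255
  voxelVolume(arr, voxelSize = meta$voxel_size_nm, origin = meta$origin_nm)
}
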