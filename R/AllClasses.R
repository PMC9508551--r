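#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib plateCT, .registration = TRUE
NULL

#' Volume metadata
#'
#' Scan-level metadata carried alongside a [CTVolume]: physical voxel size,
#' array dimensions, bit depth, slice ordering and the downsample factor at
#' which the voxel data are held. Mirrors the plain-text \file{.info} sidecar
#' written next to reconstructed slice folders (see [parseInfoFile()]).
#'
#' @slot voxelSize physical edge length of one voxel, in microns, at full
#'   (undownsampled) resolution.
#' @slot dims integer vector \code{(nSlices, nRows, nCols)} — the (z, y, x)
#'   extent of the voxel array this metadata describes (after any
#'   downsampling). May be empty when not yet known (e.g. a \file{.info} file
#'   that omits \code{dims} for a TIFF folder).
#' @slot bitDepth one of 8, 16 or 32 bits per voxel.
#' @slot sliceOrder character vector of source slice filenames in stacking
#'   order, or \code{"raw"} for a single headerless raw file.
#' @slot downsampleFactor positive integer; 1 means full resolution.
#' @seealso [parseInfoFile()], [writeInfoFile()], [readVolume()]
#' @export
setClass("VolumeMeta",
  representation(
    voxelSize = "numeric",
    dims = "integer",
    bitDepth = "integer",
    sliceOrder = "character",
    downsampleFactor = "integer"
  ),
  prototype(
    voxelSize = NA_real_,
    dims = integer(0),
    bitDepth = 8L,
    sliceOrder = "raw",
    downsampleFactor = 1L
  )
)

setValidity("VolumeMeta", function(object) {
  msg <- character(0)
  if (length(object@voxelSize) != 1 || is.na(object@voxelSize) ||
      object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number (microns)")
  if (length(object@dims) > 0 &&
      (length(object@dims) != 3 || any(is.na(object@dims)) ||
       any(object@dims < 1)))
    msg <- c(msg, "dims must be three positive integers (z, y, x)")
  if (!object@bitDepth %in% c(8L, 16L, 32L))
    msg <- c(msg, "bitDepth must be one of 8, 16, 32")
  if (length(object@downsampleFactor) != 1 || is.na(object@downsampleFactor) ||
      object@downsampleFactor < 1)
    msg <- c(msg, "downsampleFactor must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct volume metadata
#'
#' @param voxelSize physical voxel edge length in microns (full resolution).
#' @param dims integer (z, y, x) dimensions, or \code{NULL} if unknown.
#' @param bitDepth bits per voxel: 8, 16 or 32.
#' @param sliceOrder source slice filenames in order, or \code{"raw"}.
#' @param downsampleFactor positive integer stride already applied to the data.
#' @return a [VolumeMeta-class] object.
#' @examples
#' VolumeMeta(voxelSize = 48, dims = c(10, 64, 64))
#' @export
VolumeMeta <- function(voxelSize, dims = NULL, bitDepth = 8,
                       sliceOrder = "raw", downsampleFactor = 1) {
  new("VolumeMeta",
    voxelSize = as.numeric(voxelSize),
    dims = if (is.null(dims)) integer(0) else as.integer(dims),
    bitDepth = as.integer(bitDepth),
    sliceOrder = as.character(sliceOrder),
    downsampleFactor = as.integer(downsampleFactor)
  )
}

#' 3D microCT intensity volume
#'
#' A stack of reconstructed slices held as a 3D integer array indexed
#' \code{[z, y, x]} (slice, row, column; 1-based), together with its
#' [VolumeMeta-class]. When the volume was read with a downsample factor, the
#' full-resolution source location and dimensions are retained so specimens
#' can later be re-cropped at full resolution ([readSourceCrop()]).
#'
#' @slot data integer array, dim \code{(nz, ny, nx)}.
#' @slot meta a [VolumeMeta-class] describing \code{data} as held (i.e. after
#'   downsampling).
#' @slot source path of the raw file or TIFF folder the data came from
#'   (\code{NA} for in-memory volumes).
#' @slot sourceKind \code{"raw"}, \code{"tiff_folder"} or \code{"memory"}.
#' @slot sourceDims integer (z, y, x) dimensions of the full-resolution source.
#' @export
setClass("CTVolume",
  representation(
    data = "array",
    meta = "VolumeMeta",
    source = "character",
    sourceKind = "character",
    sourceDims = "integer"
  )
)

setValidity("CTVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@meta@dims) == 3 &&
      !identical(as.integer(dim(object@data)), object@meta@dims))
    msg <- c(msg, "data dimensions must equal meta dims")
  if (!object@sourceKind %in% c("raw", "tiff_folder", "memory"))
    msg <- c(msg, "sourceKind must be raw, tiff_folder or memory")
  if (length(msg)) msg else TRUE
})

#' Construct an in-memory CT volume
#'
#' @param data 3D numeric/integer array indexed \code{[z, y, x]}.
#' @param voxelSize voxel edge length in microns.
#' @param bitDepth bits per voxel (8, 16 or 32).
#' @param meta optionally a ready-made [VolumeMeta-class] (overrides
#'   \code{voxelSize}/\code{bitDepth}).
#' @return a [CTVolume-class].
#' @examples
#' v <- CTVolume(array(0L, c(4, 8, 8)), voxelSize = 48)
#' dim(v)
#' @export
CTVolume <- function(data, voxelSize = 1, bitDepth = 8, meta = NULL) {
  storage.mode(data) <- "integer"
  if (is.null(meta))
    meta <- VolumeMeta(voxelSize, dims = dim(data), bitDepth = bitDepth)
  else
    meta@dims <- as.integer(dim(data))
  new("CTVolume", data = data, meta = meta, source = NA_character_,
      sourceKind = "memory", sourceDims = as.integer(dim(data)))
}

#' Binary foreground mask
#'
#' Logical 3D array marking foreground (specimen-candidate) voxels, the output
#' of [bracketThreshold()]. Carries the downsample factor of the volume it was
#' derived from so bounding boxes can be mapped back to full resolution.
#'
#' @slot data logical array, dim \code{(nz, ny, nx)}.
#' @slot downsampleFactor downsample factor of the source volume.
#' @export
setClass("VoxelMask",
  representation(data = "array", downsampleFactor = "integer")
)

setValidity("VoxelMask", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3 || !is.logical(object@data))
    msg <- c(msg, "data must be a 3D logical array")
  if (object@downsampleFactor < 1)
    msg <- c(msg, "downsampleFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a voxel mask
#'
#' @param data 3D array; non-zero / TRUE voxels are foreground.
#' @param downsampleFactor downsample factor of the originating volume.
#' @return a [VoxelMask-class].
#' @export
VoxelMask <- function(data, downsampleFactor = 1) {
  d <- dim(data)
  data <- as.logical(data)
  dim(data) <- d
  new("VoxelMask", data = data, downsampleFactor = as.integer(downsampleFactor))
}

#' Labelled connected components (blobs)
#'
#' Result of [labelBlobs()]: an integer label array (0 = background, blob ids
#' 1..n assigned in raster order of each component's first voxel) plus a
#' per-blob statistics table.
#'
#' @slot labels integer array of blob ids, same dims as the source mask.
#' @slot blobs data.frame with one row per blob: \code{id}, \code{voxelCount},
#'   inclusive 1-based bounding box \code{z0,z1,y0,y1,x0,x1}, and centroid
#'   \code{cz,cy,cx} in continuous coordinates (voxel i is centred at
#'   i - 0.5).
#' @slot connectivity 6, 18 or 26.
#' @slot minBlobSize minimum component size (voxels) applied.
#' @slot downsampleFactor carried over from the source mask.
#' @export
setClass("BlobSet",
  representation(
    labels = "array",
    blobs = "data.frame",
    connectivity = "integer",
    minBlobSize = "integer",
    downsampleFactor = "integer"
  )
)

setValidity("BlobSet", function(object) {
  msg <- character(0)
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  b <- object@blobs
  if (nrow(b) > 0) {
    if (any(b$voxelCount < object@minBlobSize))
      msg <- c(msg, "all blobs must have voxelCount >= minBlobSize")
    inside <- b$cz >= b$z0 - 1 & b$cz <= b$z1 &
      b$cy >= b$y0 - 1 & b$cy <= b$y1 &
      b$cx >= b$x0 - 1 & b$cx <= b$x1
    if (!all(inside))
      msg <- c(msg, "blob centroids must lie within their bounding boxes")
  }
  if (length(msg)) msg else TRUE
})

#' Specimen labelling grid for one plate
#'
#' Grid of specimen ID strings mirroring the physical well layout of one
#' microtiter plate, as read from a CSV sheet ([loadLabelGrid()]), plus the 2D
#' transform placing cell centres in volume x-y coordinates.
#'
#' @slot cells character matrix (rows x cols); \code{NA} marks an empty well.
#' @slot transform list with elements \code{translate} (dx, dy voxels),
#'   \code{rotateDeg} (about the grid centre), \code{flipH}, \code{flipV},
#'   \code{pitch} (voxels per cell in x and y).
#' @slot plateIndex 1-based index of the plate this grid labels.
#' @export
setClass("LabelGrid",
  representation(cells = "matrix", transform = "list", plateIndex = "integer")
)

setValidity("LabelGrid", function(object) {
  msg <- character(0)
  if (!is.character(object@cells))
    msg <- c(msg, "cells must be a character matrix")
  tr <- object@transform
  need <- c("translate", "rotateDeg", "flipH", "flipV", "pitch")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("transform must have elements:",
                        paste(need, collapse = ", ")))
  else if (any(tr$pitch <= 0))
    msg <- c(msg, "pitch must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a grid transform
#'
#' Transform placing label-grid cell centres in volume x-y coordinates.
#' Applied in the fixed order: flips (about the grid centre), rotation (about
#' the grid centre), translation.
#'
#' @param translate numeric (dx, dy) in voxels.
#' @param rotateDeg rotation angle in degrees, counter-clockwise about the
#'   grid centre.
#' @param flipH,flipV mirror the grid horizontally (x) / vertically (y).
#' @param pitch numeric (pitchX, pitchY): voxels between adjacent well
#'   centres.
#' @return a transform list suitable for the \code{transform} slot of a
#'   [LabelGrid-class].
#' @export
gridTransform <- function(translate = c(0, 0), rotateDeg = 0,
                          flipH = FALSE, flipV = FALSE, pitch = c(1, 1)) {
  if (length(pitch) == 1) pitch <- rep(pitch, 2)
  if (length(translate) == 1) translate <- rep(translate, 2)
  stopifnot(all(pitch > 0))
  list(translate = as.numeric(translate), rotateDeg = as.numeric(rotateDeg),
       flipH = isTRUE(flipH), flipV = isTRUE(flipV),
       pitch = as.numeric(pitch))
}

#' Construct a label grid
#'
#' @param cells character matrix of specimen IDs; \code{NA} or \code{""} marks
#'   an empty well.
#' @param transform a [gridTransform()] list.
#' @param plateIndex 1-based plate index.
#' @return a [LabelGrid-class].
#' @export
LabelGrid <- function(cells, transform = gridTransform(), plateIndex = 1) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  cells[!is.na(cells) & !nzchar(trimws(cells))] <- NA_character_
  new("LabelGrid", cells = cells, transform = transform,
      plateIndex = as.integer(plateIndex))
}

#' Triangular surface mesh
#'
#' Surface mesh of one specimen, produced by [marchingCubes()] in voxel units
#' and converted to millimetres by [recentreAndScale()].
#'
#' @slot vertices numeric matrix (n x 3), columns x, y, z.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @slot units \code{"voxel"} or \code{"mm"}.
#' @slot comments character vector written as PLY comment lines (label,
#'   voxel size, units).
#' @export
setClass("SurfaceMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    units = "character",
    comments = "character"
  ),
  prototype(units = "voxel", comments = character(0))
)

setValidity("SurfaceMesh", function(object) {
  msg <- character(0)
  if (ncol(object@vertices) != 3)
    msg <- c(msg, "vertices must have 3 columns (x, y, z)")
  if (ncol(object@faces) != 3)
    msg <- c(msg, "faces must have 3 columns (triangles)")
  if (nrow(object@faces) > 0) {
    if (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices))
      msg <- c(msg, "face indices out of range")
  }
  if (!object@units %in% c("voxel", "mm"))
    msg <- c(msg, "units must be 'voxel' or 'mm'")
  if (length(msg)) msg else TRUE
})

#' Construct a surface mesh
#'
#' @param vertices numeric matrix (n x 3), columns x, y, z.
#' @param faces integer matrix (m x 3), 1-based vertex index triples.
#' @param units \code{"voxel"} or \code{"mm"}.
#' @param comments character vector of PLY comment lines.
#' @return a [SurfaceMesh-class].
#' @export
SurfaceMesh <- function(vertices, faces, units = "voxel",
                        comments = character(0)) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  colnames(vertices) <- c("x", "y", "z")
  new("SurfaceMesh", vertices = vertices, faces = faces, units = units,
      comments = as.character(comments))
}
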