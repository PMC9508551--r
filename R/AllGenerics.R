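#' Accessors for plateCT objects
#'
#' @param object,x a [CTVolume-class], [VolumeMeta-class], [VoxelMask-class],
#'   [BlobSet-class], [LabelGrid-class] or [SurfaceMesh-class] as appropriate.
#' @name accessors
NULL

#' @describeIn accessors physical voxel edge length in microns (full
#'   resolution).
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @describeIn accessors downsample factor at which the data are held.
#' @export
setGeneric("downsampleFactor",
           function(object) standardGeneric("downsampleFactor"))

#' @describeIn accessors bits per voxel.
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @describeIn accessors the underlying array (intensities, logical mask or
#'   integer labels).
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @describeIn accessors per-blob statistics table of a [BlobSet-class].
#' @export
setGeneric("blobTable", function(object) standardGeneric("blobTable"))

#' @describeIn accessors number of blobs in a [BlobSet-class].
#' @export
setGeneric("nBlobs", function(object) standardGeneric("nBlobs"))

#' @describeIn accessors vertex matrix of a [SurfaceMesh-class].
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))

#' @describeIn accessors face index matrix of a [SurfaceMesh-class].
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))

setMethod("voxelSize", "VolumeMeta", function(object) object@voxelSize)
setMethod("voxelSize", "CTVolume", function(object) object@meta@voxelSize)
setMethod("downsampleFactor", "VolumeMeta",
          function(object) object@downsampleFactor)
setMethod("downsampleFactor", "CTVolume",
          function(object) object@meta@downsampleFactor)
setMethod("downsampleFactor", "VoxelMask",
          function(object) object@downsampleFactor)
setMethod("downsampleFactor", "BlobSet",
          function(object) object@downsampleFactor)
setMethod("bitDepth", "VolumeMeta", function(object) object@bitDepth)
setMethod("bitDepth", "CTVolume", function(object) object@meta@bitDepth)
setMethod("voxelData", "CTVolume", function(object) object@data)
setMethod("voxelData", "VoxelMask", function(object) object@data)
setMethod("voxelData", "BlobSet", function(object) object@labels)
setMethod("blobTable", "BlobSet", function(object) object@blobs)
setMethod("nBlobs", "BlobSet", function(object) nrow(object@blobs))
setMethod("meshVertices", "SurfaceMesh", function(object) object@vertices)
setMethod("meshFaces", "SurfaceMesh", function(object) object@faces)

#' @describeIn accessors dimensions (z, y, x) of the held voxel data.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@data))

#' @describeIn accessors dimensions (z, y, x) of the mask.
#' @export
setMethod("dim", "VoxelMask", function(x) dim(x@data))

setMethod("show", "VolumeMeta", function(object) {
  cat("VolumeMeta:",
      sprintf("voxel %g um,", object@voxelSize),
      if (length(object@dims)) sprintf("dims %s (z,y,x),",
                                       paste(object@dims, collapse = "x"))
      else "dims unknown,",
      sprintf("%d-bit, downsample x%d\n", object@bitDepth,
              object@downsampleFactor))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %dx%dx%d (z,y,x), %d-bit, voxel %g um, downsample x%d\n",
              d[1], d[2], d[3], object@meta@bitDepth, object@meta@voxelSize,
              object@meta@downsampleFactor))
  cat(sprintf("  source: %s (%s)\n", object@source, object@sourceKind))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelMask %dx%dx%d (z,y,x), %d foreground voxels, downsample x%d\n",
              d[1], d[2], d[3], sum(object@data), object@downsampleFactor))
})

setMethod("show", "BlobSet", function(object) {
  cat(sprintf("BlobSet: %d blobs (connectivity %d, min size %d)\n",
              nrow(object@blobs), object@connectivity, object@minBlobSize))
  if (nrow(object@blobs))
    print(utils::head(object@blobs, 6))
})

setMethod("show", "LabelGrid", function(object) {
  cat(sprintf("LabelGrid plate %d: %dx%d wells, %d labelled, %d empty\n",
              object@plateIndex, nrow(object@cells), ncol(object@cells),
              sum(!is.na(object@cells)), sum(is.na(object@cells))))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, units %s\n",
              nrow(object@vertices), nrow(object@faces), object@units))
})
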