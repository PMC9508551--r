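## Segmentation: cel-shading quantisation, greyscale bracket thresholding,
## and 3D connected-component blob isolation with a minimum-size filter.

#' Cel-shading greyscale quantisation
#'
#' Quantises the image gradient by binning greyscale values downwards to
#' multiples of a base value C: \code{Xnew = X - (X mod C)}. Grouping similar
#' greys into one histogram bin simplifies the choice of a threshold and
#' suppresses noise, at the cost of possible erosion at specimen margins.
#' The operation never increases a voxel value, keeps \code{Xnew <= X <
#' Xnew + C}, and is idempotent.
#'
#' @param vol a [CTVolume-class] or numeric array/vector.
#' @param base the bin width C; integer >= 2.
#' @return same type as \code{vol}, quantised.
#' @examples
#' celShade(c(114, 52), 10)   # 110, 50
#' @export
celShade <- function(vol, base) {
  base <- as.integer(base)
  if (is.na(base) || base < 2)
    stop("cel-shading base must be an integer >= 2")
  if (is(vol, "CTVolume")) {
    out <- vol
    out@data <- vol@data - vol@data %% base
    return(out)
  }
  vol - vol %% base
}

#' Number of grey levels after cel-shading
#'
#' For a scale of \code{levels} grey values and base C, two counting
#' conventions exist: \code{floor(levels / base)} (the count of full bins),
#' and direct enumeration of the distinct outputs of \code{X - X mod C} over
#' \code{0..levels}, which is one larger whenever a partial top bin remains
#' (e.g. 255 with base 10: floor gives 25, enumeration gives 26 distinct
#' values \{0, 10, ..., 250\}). Both are exposed; the floor convention is the
#' one conventionally quoted.
#'
#' @param levels top grey value of the scale (255 for 8-bit).
#' @param base the cel-shading base C.
#' @param convention \code{"floor"} or \code{"enumerate"}.
#' @return integer count of grey levels.
#' @examples
#' celShadeLevels(255, 10)                       # 25
#' celShadeLevels(255, 10, "enumerate")          # 26
#' @export
celShadeLevels <- function(levels = 255, base, convention = c("floor",
                                                              "enumerate")) {
  convention <- match.arg(convention)
  base <- as.integer(base)
  stopifnot(base >= 2)
  switch(convention,
    floor = levels %/% base,
    enumerate = length(unique(celShade(0:levels, base))))
}

#' Greyscale bracket thresholding
#'
#' Keeps as foreground exactly the voxels inside the bracket
#' \code{[tLower, tUpper]}; everything below the lower or above the upper
#' threshold is zeroed. The two one-sided thresholds deployed together let
#' the user select the specimen peak of the histogram while excluding both
#' the mount below and any bright artefacts above.
#'
#' @param vol a [CTVolume-class] or numeric array.
#' @param tLower,tUpper inclusive bracket bounds, \code{tLower <= tUpper}.
#' @return a [VoxelMask-class] (for a [CTVolume-class] input) or logical
#'   array.
#' @examples
#' bracketThreshold(c(0, 31, 52, 114, 255), 52, 255)  # F F T T T
#' @export
bracketThreshold <- function(vol, tLower, tUpper) {
  if (tLower > tUpper) stop("tLower must be <= tUpper")
  if (is(vol, "CTVolume")) {
    m <- vol@data >= tLower & vol@data <= tUpper
    dim(m) <- dim(vol@data)
    return(VoxelMask(m, downsampleFactor = vol@meta@downsampleFactor))
  }
  vol >= tLower & vol <= tUpper
}

#' Isolate specimens as 3D connected components (blobs)
#'
#' Labels maximal connected components of the foreground under 6-, 18- or
#' 26-connectivity, discards components smaller than \code{minBlobSize}
#' voxels (removing residual mount fragments and noise specks below the
#' smallest real specimen), and assigns ids 1..n in raster order of each
#' component's first voxel (slices, then rows, then columns), so exports are
#' reproducible.
#'
#' @param mask a [VoxelMask-class] or logical 3D array.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners; default —
#'   diagonally touching fragments of one specimen stay together).
#' @param minBlobSize minimum component size in working-resolution voxels.
#' @return a [BlobSet-class]; an empty mask yields zero blobs (not an error).
#' @details Centroids are arithmetic means of member voxel centres in the
#'   continuous frame (voxel i centred at i - 0.5); bounding boxes are
#'   1-based inclusive index ranges.
#' @export
labelBlobs <- function(mask, connectivity = 26, minBlobSize = 1) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  minBlobSize <- as.integer(minBlobSize)
  stopifnot(minBlobSize >= 1)
  dsf <- if (is(mask, "VoxelMask")) mask@downsampleFactor else 1L
  arr <- if (is(mask, "VoxelMask")) mask@data else mask
  stopifnot(length(dim(arr)) == 3)
  storage.mode(arr) <- "integer"

  labels <- cpp_label3d(arr, dim(arr), connectivity)
  dim(labels) <- dim(arr)

  stats <- cpp_blob_stats(labels, dim(arr))
  keep <- which(stats$count >= minBlobSize)
  blobs <- data.frame(
    id = seq_along(keep),
    voxelCount = stats$count[keep],
    z0 = stats$z0[keep], z1 = stats$z1[keep],
    y0 = stats$y0[keep], y1 = stats$y1[keep],
    x0 = stats$x0[keep], x1 = stats$x1[keep],
    cz = stats$cz[keep] - 0.5, cy = stats$cy[keep] - 0.5,
    cx = stats$cx[keep] - 0.5)

  ## relabel: dropped components -> 0, kept -> 1..n (raster order preserved,
  ## since cpp_label3d already assigns ids in raster order of first voxel)
  remap <- integer(length(stats$count))
  remap[keep] <- seq_along(keep)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  dim(labels) <- dim(arr)

  new("BlobSet", labels = labels, blobs = blobs,
      connectivity = connectivity, minBlobSize = minBlobSize,
      downsampleFactor = as.integer(dsf))
}

#' Extract one blob's mask
#'
#' @param blobSet a [BlobSet-class].
#' @param id blob id.
#' @param crop if \code{TRUE}, return only the blob's bounding box.
#' @return a [VoxelMask-class] of that blob alone.
#' @export
blobMask <- function(blobSet, id, crop = FALSE) {
  b <- blobSet@blobs[blobSet@blobs$id == id, ]
  if (nrow(b) != 1) stop(sprintf("no blob with id %d", id))
  m <- blobSet@labels == id
  dim(m) <- dim(blobSet@labels)
  if (crop)
    m <- m[b$z0:b$z1, b$y0:b$y1, b$x0:b$x1, drop = FALSE]
  VoxelMask(m, downsampleFactor = blobSet@downsampleFactor)
}
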