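## Full-resolution re-crop and per-specimen TIFF stack export in three modes
## (raw, mask, processed), with a manifest for traceability.

#' Scale a working-resolution bounding box to full resolution
#'
#' The working template is downsampled by an integer stride, so working voxel
#' i covers full-resolution voxels \code{(i-1)f + 1 .. i f}. Lower bounds are
#' additionally widened by \code{margin} full-resolution voxels and upper
#' bounds likewise, then clamped to the volume, so blurred partial-volume
#' halos survive the crop.
#'
#' @param bbox named vector \code{(z0, z1, y0, y1, x0, x1)}, 1-based
#'   inclusive, working resolution (a row of [blobTable()] works).
#' @param factor the downsample factor f.
#' @param margin full-resolution voxels of padding (default 2).
#' @param fullDims full-resolution (z, y, x) dimensions for clamping.
#' @return named integer vector \code{(z0, z1, y0, y1, x0, x1)}, 1-based
#'   inclusive, full resolution.
#' @export
scaleBboxToFull <- function(bbox, factor, margin = 2,
                            fullDims = c(Inf, Inf, Inf)) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  lo <- c(bbox[["z0"]], bbox[["y0"]], bbox[["x0"]])
  hi <- c(bbox[["z1"]], bbox[["y1"]], bbox[["x1"]])
  lo <- (lo - 1L) * factor + 1L - margin
  hi <- hi * factor + margin
  lo <- pmax(lo, 1)
  hi <- pmin(hi, fullDims)
  out <- as.integer(c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]))
  names(out) <- c("z0", "z1", "y0", "y1", "x0", "x1")
  out
}

## map label strings to filesystem-safe ASCII names: anything outside
## [A-Za-z0-9._-] becomes "_"
sanitiseLabel <- function(label) {
  out <- gsub("[^A-Za-z0-9._-]", "_", label)
  out[!nzchar(out)] <- "_"
  out
}

## nearest-neighbour upscale of one blob's working mask into a
## full-resolution crop: full voxel I maps to working voxel floor((I-1)/f)+1
upscaleBlobMask <- function(labels, id, bboxFull, factor) {
  zs <- bboxFull[["z0"]]:bboxFull[["z1"]]
  ys <- bboxFull[["y0"]]:bboxFull[["y1"]]
  xs <- bboxFull[["x0"]]:bboxFull[["x1"]]
  d <- dim(labels)
  wz <- pmin(pmax((zs - 1L) %/% factor + 1L, 1L), d[1])
  wy <- pmin(pmax((ys - 1L) %/% factor + 1L, 1L), d[2])
  wx <- pmin(pmax((xs - 1L) %/% factor + 1L, 1L), d[3])
  m <- labels[wz, wy, wx, drop = FALSE] == id
  dim(m) <- c(length(zs), length(ys), length(xs))
  m
}

#' Export labelled specimens as full-resolution TIFF stacks
#'
#' For every assignment, re-crops the original full-resolution data at the
#' blob's scaled bounding box and writes per-specimen 8-bit TIFF stacks in
#' the requested modes:
#' \describe{
#'   \item{raw}{the cropped original data, unprocessed (may include mount).}
#'   \item{mask}{the blob's binary mask as a \{0, 255\} stack
#'     (nearest-neighbour upscaled from the working resolution).}
#'   \item{processed}{original voxels inside the mask, 0 outside — i.e.
#'     raw voxelwise-multiplied by mask/255.}
#' }
#' Output layout: \code{outDir/<label>/<mode>/<label>_<mode>_<slice>.tif},
#' with filenames rooted at the assigned specimen ID, plus a
#' \file{manifest.csv} (label, plate, cell, bbox, voxel size) for
#' traceability.
#'
#' @param vol the [CTVolume-class] whose source holds the full-resolution
#'   data (8-bit; convert with [to8bit()] first if needed).
#' @param blobSet the [BlobSet-class] from [labelBlobs()].
#' @param assignments data.frame from [assignLabels()].
#' @param modes subset of \code{c("raw", "mask", "processed")}.
#' @param outDir output directory.
#' @param margin full-resolution voxels of bounding-box padding.
#' @return invisibly, the manifest data.frame.
#' @export
exportSpecimens <- function(vol, blobSet, assignments,
                            modes = c("raw", "mask", "processed"),
                            outDir, margin = 2) {
  modes <- match.arg(modes, c("raw", "mask", "processed"),
                     several.ok = TRUE)
  if (vol@meta@bitDepth != 8L)
    stop("export is 8-bit; convert the volume with to8bit() first")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  f <- blobSet@downsampleFactor
  fullDims <- vol@sourceDims
  safe <- sanitiseLabel(assignments$label)
  if (anyDuplicated(safe))
    stop("specimen output directory collision after sanitising labels; ",
         "labels should be unique upstream")

  rows <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    b <- blobSet@blobs[blobSet@blobs$id == a$blobId, ]
    bboxFull <- scaleBboxToFull(b, f, margin, fullDims)
    crop <- readSourceCrop(vol, bboxFull)
    m <- upscaleBlobMask(blobSet@labels, a$blobId, bboxFull, f)
    nz <- dim(crop)[1]
    width <- max(4L, nchar(as.character(nz)))
    for (mode in modes) {
      mdir <- file.path(outDir, safe[i], mode)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      stack <- switch(mode,
        raw = crop,
        mask = 255L * m,
        processed = crop * m)
      dim(stack) <- dim(crop)
      for (z in seq_len(nz))
        tiff::writeTIFF(stack[z, , ] / 255,
                        file.path(mdir, sprintf("%s_%s_%0*d.tif",
                                                safe[i], mode, width, z)),
                        bits.per.sample = 8L)
    }
    rows[[i]] <- data.frame(
      label = a$label, dir = safe[i], plateIndex = a$plateIndex,
      row = a$row, col = a$col,
      z0 = bboxFull[["z0"]], z1 = bboxFull[["z1"]],
      y0 = bboxFull[["y0"]], y1 = bboxFull[["y1"]],
      x0 = bboxFull[["x0"]], x1 = bboxFull[["x1"]],
      voxelCount = b$voxelCount, voxelSizeUm = vol@meta@voxelSize,
      modes = paste(modes, collapse = ";"), status = "ok",
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
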