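## Volume import/export: .info sidecar, raw and TIFF-folder readers,
## stride downsampling, bit-depth conversion, TIFF stack writer.

#' Parse a .info metadata sidecar
#'
#' Reconstructed microCT slice folders carry no scale information, so a
#' plain-text \file{.info} file next to the data records it: UTF-8
#' \code{key=value} lines. Recognised keys: \code{voxel_size_um} (mandatory),
#' \code{dims} (\code{z,y,x}), \code{bit_depth}, \code{downsample_factor},
#' \code{slice_order} (comma-separated filenames, or \code{raw}). Unknown keys
#' are tolerated so vendor-generated files can be pointed at directly.
#'
#' @param text the file contents as a single string (or character vector of
#'   lines).
#' @return a [VolumeMeta-class].
#' @section Errors: a missing \code{voxel_size_um} raises a condition of class
#'   \code{plateCT_metadata_absent}, so callers can catch it, obtain the voxel
#'   size elsewhere and regenerate the file with [writeInfoFile()].
#' @examples
#' parseInfoFile("voxel_size_um=48\ndims=10,64,64\nbit_depth=8")
#' @export
parseInfoFile <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m)) trimws(m[2]) else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m)) trimws(m[3]) else NA_character_,
                 character(1))
  ok <- !is.na(keys)
  keys <- keys[ok]; vals <- vals[ok]
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL

  vs <- get("voxel_size_um")
  if (is.null(vs) || !nzchar(vs) || is.na(suppressWarnings(as.numeric(vs))))
    stop(metadataAbsentCondition(
      "mandatory key 'voxel_size_um' missing from .info metadata"))

  dims <- get("dims")
  dims <- if (is.null(dims)) NULL else as.integer(strsplit(dims, ",")[[1]])
  so <- get("slice_order")
  so <- if (is.null(so)) "raw" else trimws(strsplit(so, ",")[[1]])
  VolumeMeta(
    voxelSize = as.numeric(vs),
    dims = dims,
    bitDepth = if (is.null(get("bit_depth"))) 8 else as.integer(get("bit_depth")),
    sliceOrder = so,
    downsampleFactor = if (is.null(get("downsample_factor"))) 1
                       else as.integer(get("downsample_factor"))
  )
}

metadataAbsentCondition <- function(msg) {
  structure(class = c("plateCT_metadata_absent", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Serialise volume metadata to .info text
#'
#' Inverse of [parseInfoFile()]: \code{parseInfoFile(writeInfoFile(m))} is
#' identical to \code{m}. Can regenerate a missing sidecar internally.
#'
#' @param meta a [VolumeMeta-class].
#' @param path optional file to write the text to.
#' @return the \file{.info} text, invisibly when \code{path} is given.
#' @export
writeInfoFile <- function(meta, path = NULL) {
  stopifnot(is(meta, "VolumeMeta"))
  validObject(meta)
  lines <- c(
    sprintf("voxel_size_um=%s", format(meta@voxelSize, digits = 15)),
    if (length(meta@dims))
      sprintf("dims=%s", paste(meta@dims, collapse = ",")),
    sprintf("bit_depth=%d", meta@bitDepth),
    sprintf("downsample_factor=%d", meta@downsampleFactor),
    sprintf("slice_order=%s", paste(meta@sliceOrder, collapse = ","))
  )
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

## numeric-aware (natural) sort: "slice2" < "slice10"
naturalSort <- function(x) {
  parts <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  maxlen <- max(lengths(parts))
  keys <- lapply(seq_len(maxlen), function(i) {
    p <- vapply(parts, function(v) if (i <= length(v)) v[i] else "",
                character(1))
    num <- suppressWarnings(as.numeric(p))
    if (all(!is.na(num) | p == "")) ifelse(p == "", -Inf, num) else p
  })
  x[do.call(order, keys)]
}

bytesPerVoxel <- function(bitDepth) as.integer(bitDepth) %/% 8L

#' Read a microCT volume
#'
#' Reads either a single headerless raw file or a folder of single-slice
#' grayscale TIFFs into a [CTVolume-class], optionally stride-downsampling on
#' load so a large scan can act as a working template. The source path and
#' full-resolution dimensions are retained on the object so specimens can be
#' re-cropped at full resolution later ([readSourceCrop()]).
#'
#' @param path the raw file, or the TIFF folder.
#' @param kind \code{"auto"} (folder => \code{"tiff_folder"}),
#'   \code{"raw"} or \code{"tiff_folder"}.
#' @param meta a [VolumeMeta-class]; mandatory for raw input (headerless, so
#'   \code{dims} and \code{bitDepth} must be supplied). If \code{NULL} for a
#'   TIFF folder, a \file{.info} file inside the folder is parsed if present.
#' @param downsampleFactor positive integer stride applied on load; the
#'   returned volume has \code{floor(dim / factor)} voxels per axis.
#' @return a [CTVolume-class]; \code{meta@dims} describe the data as held
#'   (after downsampling), \code{sourceDims} the full-resolution extent.
#' @details TIFF slices are stacked in natural (numeric-aware) filename order,
#'   overridable by an explicit \code{slice_order} in the \file{.info} file.
#'   Raw files are voxel-major with x fastest, then y, then z. A raw file
#'   whose size does not equal \code{prod(dims) * bytesPerVoxel}, or a TIFF
#'   slice whose dimensions differ from the first slice, is a hard error.
#' @export
readVolume <- function(path, kind = c("auto", "raw", "tiff_folder"),
                       meta = NULL, downsampleFactor = 1) {
  kind <- match.arg(kind)
  if (kind == "auto")
    kind <- if (dir.exists(path)) "tiff_folder" else "raw"
  downsampleFactor <- as.integer(downsampleFactor)
  stopifnot(downsampleFactor >= 1)

  if (kind == "raw") {
    if (is.null(meta) || length(meta@dims) != 3)
      stop("raw input is headerless: supply meta with dims and bitDepth")
    dims <- meta@dims
    bpv <- bytesPerVoxel(meta@bitDepth)
    expect <- prod(as.numeric(dims)) * bpv
    actual <- file.info(path)$size
    if (is.na(actual) || actual != expect)
      stop(sprintf(
        "raw file '%s' is %s bytes but dims %s at %d-bit require %s bytes",
        path, format(actual), paste(dims, collapse = "x"), meta@bitDepth,
        format(expect)))
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, what = "integer", n = prod(as.numeric(dims)),
                 size = bpv, signed = meta@bitDepth == 32L,
                 endian = "little")
    # source layout: x fastest, then y, then z -> array (x,y,z), flip to (z,y,x)
    arr <- array(v, dim = c(dims[3], dims[2], dims[1]))
    arr <- aperm(arr, c(3, 2, 1))
    sliceOrder <- "raw"
  } else {
    if (is.null(meta)) {
      info <- file.path(path, ".info")
      if (!file.exists(info))
        info <- list.files(path, pattern = "\\.info$", full.names = TRUE)[1]
      if (length(info) == 1 && !is.na(info) && file.exists(info))
        meta <- parseInfoFile(readLines(info, warn = FALSE))
      else
        stop(metadataAbsentCondition(
          sprintf("no meta supplied and no .info file found in '%s'", path)))
    }
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE)
    if (!identical(meta@sliceOrder, "raw") &&
        all(meta@sliceOrder %in% files))
      files <- meta@sliceOrder
    else
      files <- naturalSort(files)
    if (length(files) == 0)
      stop(sprintf("no TIFF slices found in '%s'", path))
    first <- readTiffSlice(file.path(path, files[1]))
    dimYX <- dim(first)
    arr <- array(0L, dim = c(length(files), dimYX[1], dimYX[2]))
    arr[1, , ] <- first
    if (length(files) > 1) {
      for (i in 2:length(files)) {
        sl <- readTiffSlice(file.path(path, files[i]))
        if (!identical(dim(sl), dimYX))
          stop(sprintf(
            "slice '%s' is %dx%d but first slice '%s' is %dx%d",
            files[i], dim(sl)[1], dim(sl)[2], files[1], dimYX[1], dimYX[2]))
        arr[i, , ] <- sl
      }
    }
    meta@dims <- as.integer(dim(arr))
    sliceOrder <- files
  }

  fullDims <- as.integer(dim(arr))
  if (downsampleFactor > 1)
    arr <- strideSample(arr, downsampleFactor)
  meta@dims <- as.integer(dim(arr))
  meta@sliceOrder <- sliceOrder
  meta@downsampleFactor <- downsampleFactor
  storage.mode(arr) <- "integer"
  new("CTVolume", data = arr, meta = meta,
      source = normalizePath(path), sourceKind = kind, sourceDims = fullDims)
}

## read one grayscale TIFF slice as an integer [y, x] matrix
readTiffSlice <- function(file) {
  m <- tiff::readTIFF(file, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]  # drop extra channels if present
  storage.mode(m) <- "integer"
  m
}

strideSample <- function(arr, f) {
  d <- dim(arr)
  if (any(f > d))
    stop(sprintf("downsample factor %d exceeds volume extent (%s)",
                 f, paste(d, collapse = "x")))
  idx <- lapply(d, function(n) (seq_len(n %/% f) - 1L) * f + 1L)
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

blockMean <- function(arr, f) {
  d <- dim(arr)
  nd <- d %/% f
  if (any(nd < 1))
    stop(sprintf("downsample factor %d exceeds volume extent (%s)",
                 f, paste(d, collapse = "x")))
  a <- arr[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
           drop = FALSE]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  round(out)
}

#' Downsample a volume
#'
#' Stride (nearest) sampling: output voxel \code{(i, j, k)} is input voxel
#' \code{((i-1)f + 1, (j-1)f + 1, (k-1)f + 1)}; each axis keeps
#' \code{floor(n / f)} voxels. Factor 1 is the identity. The downsampled
#' volume is a working template only — exports always re-crop the
#' full-resolution source. Block-mean averaging is available via
#' \code{method = "mean"}.
#'
#' @param vol a [CTVolume-class].
#' @param factor positive integer.
#' @param method \code{"stride"} (default) or \code{"mean"}.
#' @return a [CTVolume-class] with the compounded \code{downsampleFactor}.
#' @export
downsampleVolume <- function(vol, factor, method = c("stride", "mean")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(vol)
  arr <- switch(method,
    stride = strideSample(vol@data, factor),
    mean = blockMean(vol@data, factor))
  storage.mode(arr) <- "integer"
  meta <- vol@meta
  meta@dims <- as.integer(dim(arr))
  meta@downsampleFactor <- meta@downsampleFactor * factor
  new("CTVolume", data = arr, meta = meta, source = vol@source,
      sourceKind = vol@sourceKind, sourceDims = vol@sourceDims)
}

#' Convert a volume to 8-bit
#'
#' Linear min–max rescale to \code{[0, 255]}: 8-bit input is passed through
#' unchanged; other depths map \code{x} to
#' \code{round(255 (x - min) / (max - min))}; a constant volume maps to 0.
#' The mapping is monotone, so thresholding order relations survive.
#'
#' @param vol a [CTVolume-class].
#' @return an 8-bit [CTVolume-class].
#' @export
to8bit <- function(vol) {
  if (vol@meta@bitDepth == 8L) return(vol)
  arr <- vol@data
  rng <- range(arr)
  arr <- if (rng[1] == rng[2]) array(0L, dim(arr))
         else as.integer(round(255 * (as.numeric(arr) - rng[1]) /
                                 (rng[2] - rng[1])))
  dim(arr) <- dim(vol@data)
  meta <- vol@meta
  meta@bitDepth <- 8L
  new("CTVolume", data = arr, meta = meta, source = vol@source,
      sourceKind = vol@sourceKind, sourceDims = vol@sourceDims)
}

#' Write a volume as an 8-bit TIFF stack
#'
#' One grayscale TIFF per slice with zero-padded numeric suffixes, plus a
#' \file{.info} sidecar, so the folder can be re-read with [readVolume()].
#'
#' @param vol an 8-bit [CTVolume-class] (convert with [to8bit()] first).
#' @param dir output folder (created if needed).
#' @param prefix slice filename prefix.
#' @param compression \code{"none"} or \code{"deflate"}.
#' @return invisibly, the slice filenames written.
#' @export
writeVolume <- function(vol, dir, prefix = "slice", compression = "none") {
  if (vol@meta@bitDepth != 8L)
    stop("writeVolume exports 8-bit stacks; call to8bit() first")
  compression <- match.arg(compression, c("none", "deflate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol@data)
  width <- max(4L, nchar(as.character(d[1])))
  files <- sprintf("%s_%0*d.tif", prefix, width, seq_len(d[1]))
  for (z in seq_len(d[1])) {
    tiff::writeTIFF(vol@data[z, , ] / 255, file.path(dir, files[z]),
                    bits.per.sample = 8L, compression = compression)
  }
  meta <- vol@meta
  meta@sliceOrder <- files
  writeInfoFile(meta, file.path(dir, ".info"))
  invisible(files)
}

#' Re-crop a bounding box from the full-resolution source
#'
#' A volume read with a downsample factor keeps only the working template in
#' memory; this reads the given full-resolution bounding box back from the
#' original raw file or TIFF folder (slice by slice, so the whole scan is
#' never loaded).
#'
#' @param vol the [CTVolume-class] whose \code{source} to re-read. An
#'   in-memory volume at factor 1 is cropped directly.
#' @param bbox named numeric vector \code{(z0, z1, y0, y1, x0, x1)}, 1-based
#'   inclusive, in full-resolution voxel indices.
#' @return an integer array of the cropped full-resolution intensities.
#' @export
readSourceCrop <- function(vol, bbox) {
  b <- as.integer(bbox[c("z0", "z1", "y0", "y1", "x0", "x1")])
  fd <- vol@sourceDims
  if (any(b[c(1, 3, 5)] < 1) || b[2] > fd[1] || b[4] > fd[2] || b[6] > fd[3])
    stop("bbox out of full-resolution bounds")
  zs <- b[1]:b[2]; ys <- b[3]:b[4]; xs <- b[5]:b[6]
  if (vol@sourceKind == "memory" || vol@meta@downsampleFactor == 1L)
    return(vol@data[zs, ys, xs, drop = FALSE])
  out <- array(0L, c(length(zs), length(ys), length(xs)))
  if (vol@sourceKind == "tiff_folder") {
    files <- vol@meta@sliceOrder
    for (i in seq_along(zs)) {
      sl <- readTiffSlice(file.path(vol@source, files[zs[i]]))
      out[i, , ] <- sl[ys, xs]
    }
  } else {
    bpv <- bytesPerVoxel(vol@meta@bitDepth)
    con <- file(vol@source, "rb")
    on.exit(close(con))
    sliceN <- as.numeric(fd[2]) * fd[3]
    for (i in seq_along(zs)) {
      seek(con, where = (zs[i] - 1) * sliceN * bpv)
      v <- readBin(con, "integer", n = sliceN, size = bpv,
                   signed = vol@meta@bitDepth == 32L, endian = "little")
      sl <- array(v, dim = c(fd[3], fd[2]))  # x fastest
      out[i, , ] <- t(sl)[ys, xs]
    }
  }
  out
}
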