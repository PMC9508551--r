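## Plate detection along z, CSV label grids and their 2D transforms, and
## nearest-centroid assignment of specimen IDs to blobs.

#' Detect stacked plates from z-gaps
#'
#' Plates stacked in z are separated by empty gaps, so a slice is "occupied"
#' iff its foreground pixel count is at least \code{minBlobSize}; maximal runs
#' of occupied slices become plates, in z order. A plate's centre slice is the
#' midpoint of its run (a half-integer for even-length runs; used only for
#' plate/grid pairing, never as an index).
#'
#' @param mask a [VoxelMask-class] or logical 3D array.
#' @param minBlobSize per-slice pixel count below which a slice counts as
#'   empty (same working resolution as the blob-size filter).
#' @return data.frame with \code{plateIndex} (1-based), \code{startSlice},
#'   \code{endSlice} (1-based inclusive) and \code{centreSlice}; zero rows if
#'   no slice is occupied.
#' @export
detectPlates <- function(mask, minBlobSize = 1) {
  arr <- if (is(mask, "VoxelMask")) mask@data else mask
  counts <- rowSums(arr, dims = 1)
  plateSpansFromCounts(counts, minBlobSize)
}

#' Plate spans from a per-slice count sequence
#'
#' The 1D core of [detectPlates()], exposed so the run-length rule can be
#' applied (and property-tested) on bare count sequences.
#'
#' @param counts numeric vector of per-slice foreground pixel counts.
#' @param minBlobSize occupancy threshold.
#' @return same as [detectPlates()].
#' @examples
#' plateSpansFromCounts(c(0, 0, 5, 9, 8, 0, 0, 7, 7, 0), 3)
#' @export
plateSpansFromCounts <- function(counts, minBlobSize = 1) {
  occupied <- counts >= minBlobSize
  if (!any(occupied))
    return(data.frame(plateIndex = integer(0), startSlice = integer(0),
                      endSlice = integer(0), centreSlice = numeric(0)))
  r <- rle(occupied)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(plateIndex = seq_len(sum(keep)),
             startSlice = starts[keep], endSlice = ends[keep],
             centreSlice = (starts[keep] + ends[keep]) / 2)
}

#' Load a specimen label grid from CSV
#'
#' One CSV sheet per plate, its grid of cells mirroring the physical well
#' layout (RFC-4180, no header row: every row is a plate row). Blank or
#' whitespace-only cells mark empty wells. The returned grid carries the
#' identity transform (unit pitch, no rotation/flip/translation); place it
#' over the volume with [setGridTransform()].
#'
#' @param csv path to a CSV file, or the CSV text itself (anything containing
#'   a newline or comma is treated as text).
#' @param plateIndex 1-based plate this sheet labels.
#' @return a [LabelGrid-class].
#' @section Errors: a ragged CSV (rows of unequal length) is a hard error
#'   naming the offending row; duplicate non-empty labels within one sheet
#'   are a hard error (specimen IDs must be unique).
#' @export
loadLabelGrid <- function(csv, plateIndex = 1) {
  isText <- grepl("[,\n]", csv[1]) || length(csv) > 1
  lines <- if (isText) unlist(strsplit(paste(csv, collapse = "\n"), "\n"))
           else readLines(csv, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(lines)))
    stop("label CSV is empty")
  nf <- utils::count.fields(textConnection(lines), sep = ",",
                            quote = "\"", blank.lines.skip = FALSE)
  nf[is.na(nf)] <- 0L
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged label CSV: row %d has %d cells but row 1 has %d",
                 bad, nf[bad], nf[1]))
  }
  cells <- as.matrix(utils::read.csv(textConnection(lines), header = FALSE,
                                     colClasses = "character",
                                     blank.lines.skip = FALSE))
  dimnames(cells) <- NULL
  cells <- trimws(cells)
  cells[!nzchar(cells)] <- NA_character_
  labs <- cells[!is.na(cells)]
  if (anyDuplicated(labs))
    stop(sprintf("duplicate specimen IDs in label CSV: %s",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  LabelGrid(cells, plateIndex = plateIndex)
}

#' Set or replace a grid's placing transform
#'
#' @param grid a [LabelGrid-class].
#' @param ... arguments to [gridTransform()], or a single ready-made
#'   transform list.
#' @return the grid with the new transform.
#' @export
setGridTransform <- function(grid, ...) {
  args <- list(...)
  grid@transform <- if (length(args) == 1 && is.list(args[[1]]) &&
                        "pitch" %in% names(args[[1]])) args[[1]]
                    else do.call(gridTransform, args)
  validObject(grid)
  grid
}

#' Transformed cell-centre coordinates
#'
#' The centre of cell (r, c) starts at
#' \code{((c - 0.5) pitchX, (r - 0.5) pitchY)} (1-based rows/cols in the
#' continuous frame with the grid corner at the origin), then the transform
#' is applied in the fixed order: flips about the grid centre, rotation about
#' the grid centre, translation.
#'
#' @param grid a [LabelGrid-class].
#' @return data.frame with \code{row}, \code{col}, \code{label} (\code{NA}
#'   for empty wells), \code{x}, \code{y}.
#' @export
cellCentres <- function(grid) {
  R <- nrow(grid@cells); C <- ncol(grid@cells)
  tr <- grid@transform
  g <- expand.grid(row = seq_len(R), col = seq_len(C))
  x <- (g$col - 0.5) * tr$pitch[1]
  y <- (g$row - 0.5) * tr$pitch[2]
  cx <- C * tr$pitch[1] / 2
  cy <- R * tr$pitch[2] / 2
  if (tr$flipH) x <- 2 * cx - x
  if (tr$flipV) y <- 2 * cy - y
  if (tr$rotateDeg != 0) {
    th <- tr$rotateDeg * pi / 180
    dx <- x - cx; dy <- y - cy
    x <- cx + cos(th) * dx - sin(th) * dy
    y <- cy + sin(th) * dx + cos(th) * dy
  }
  x <- x + tr$translate[1]
  y <- y + tr$translate[2]
  data.frame(row = g$row, col = g$col,
             label = grid@cells[cbind(g$row, g$col)], x = x, y = y,
             stringsAsFactors = FALSE)
}

#' Corner labels for mirror-image verification
#'
#' Returns the IDs at the four grid corners after flips, for display and
#' logging, so a user can verify against the physical plate that the scan is
#' not mirrored. Purely informational: no auto-correction is attempted.
#'
#' @param grid a non-empty [LabelGrid-class].
#' @return named character(4): \code{topLeft}, \code{topRight},
#'   \code{bottomLeft}, \code{bottomRight}.
#' @export
cornerLabels <- function(grid) {
  cells <- grid@cells
  if (grid@transform$flipH) cells <- cells[, rev(seq_len(ncol(cells))),
                                           drop = FALSE]
  if (grid@transform$flipV) cells <- cells[rev(seq_len(nrow(cells))), ,
                                           drop = FALSE]
  R <- nrow(cells); C <- ncol(cells)
  c(topLeft = cells[1, 1], topRight = cells[1, C],
    bottomLeft = cells[R, 1], bottomRight = cells[R, C])
}

#' Assign specimen IDs to blobs
#'
#' Each blob is attributed to the plate whose z-span contains its centroid
#' (nearest span if it sits in a gap), then matched to the nearest non-empty
#' cell centre of that plate's grid in x-y Euclidean distance. A cell matched
#' by exactly one blob passes its label on unchanged; a cell matched by k > 1
#' blobs (the doubled-well case) yields suffixed labels
#' \code{label_1 ... label_k} ordered by ascending distance. Blobs farther
#' than \code{maxMatchDistance} from every cell — and all blobs when no grid
#' is supplied — fall back to sequential numeric labels
#' \code{specimen_0001, ...}: data is never silently dropped. Empty cells
#' never receive a blob.
#'
#' @param blobs a [BlobSet-class] or its [blobTable()] data.frame.
#' @param grids list of [LabelGrid-class], one per detected plate in z order,
#'   or \code{NULL} for pure numeric labelling. Individual list entries may
#'   also be \code{NULL}.
#' @param spans plate spans from [detectPlates()].
#' @param maxMatchDistance voxels; default 0.75 of the smaller grid pitch.
#' @return data.frame with one row per blob: \code{blobId}, \code{plateIndex},
#'   \code{row}, \code{col} (\code{NA} when unmatched), \code{label},
#'   \code{distance}.
#' @details Ties (two cells equidistant from a blob) resolve to the first
#'   cell in row-major order. Output labels are globally unique: should the
#'   same ID appear on two plates' sheets, later occurrences are suffixed.
#' @export
assignLabels <- function(blobs, grids, spans, maxMatchDistance = NULL) {
  tab <- if (is(blobs, "BlobSet")) blobTable(blobs) else blobs
  if (!is.null(grids) && length(grids) != nrow(spans))
    stop(sprintf("%d label grids supplied for %d detected plates",
                 length(grids), nrow(spans)))
  if (nrow(tab) == 0)
    return(data.frame(blobId = integer(0), plateIndex = integer(0),
                      row = integer(0), col = integer(0),
                      label = character(0), distance = numeric(0)))

  ## blob -> plate: span containing the centroid z, else nearest span.
  ## centroid cz is continuous (voxel i spans (i-1, i]), span is index range.
  plateOf <- vapply(tab$cz, function(cz) {
    inSpan <- which(cz > spans$startSlice - 1 & cz <= spans$endSlice)
    if (length(inSpan)) return(spans$plateIndex[inSpan[1]])
    d <- pmax(spans$startSlice - 1 - cz, cz - spans$endSlice, 0)
    spans$plateIndex[which.min(d)]
  }, numeric(1))

  out <- data.frame(blobId = tab$id, plateIndex = as.integer(plateOf),
                    row = NA_integer_, col = NA_integer_,
                    label = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)

  for (p in spans$plateIndex) {
    rows <- which(out$plateIndex == p)
    if (!length(rows)) next
    grid <- if (is.null(grids)) NULL else grids[[match(p, spans$plateIndex)]]
    if (is.null(grid)) next
    cen <- cellCentres(grid)
    cen <- cen[!is.na(cen$label), , drop = FALSE]
    if (nrow(cen) == 0) next
    maxd <- if (is.null(maxMatchDistance))
      0.75 * min(grid@transform$pitch) else maxMatchDistance
    ## row-major order so which.min tie-breaks to the first row-major cell
    cen <- cen[order(cen$row, cen$col), , drop = FALSE]
    for (i in rows) {
      d <- sqrt((cen$x - tab$cx[tab$id == out$blobId[i]])^2 +
                (cen$y - tab$cy[tab$id == out$blobId[i]])^2)
      j <- which.min(d)
      if (d[j] <= maxd) {
        out$row[i] <- cen$row[j]
        out$col[i] <- cen$col[j]
        out$label[i] <- cen$label[j]
        out$distance[i] <- d[j]
      }
    }
    ## doubled wells: suffix _1.._k by ascending distance
    key <- paste(out$plateIndex[rows], out$row[rows], out$col[rows])
    key[is.na(out$label[rows])] <- NA
    for (k in unique(key[!is.na(key)])) {
      hit <- rows[!is.na(key) & key == k]
      if (length(hit) > 1) {
        ord <- hit[order(out$distance[hit])]
        out$label[ord] <- paste0(out$label[ord], "_", seq_along(ord))
      }
    }
  }

  ## numeric fallback for unmatched blobs (and all blobs when grid is NULL)
  unmatched <- which(is.na(out$label))
  if (length(unmatched))
    out$label[unmatched] <- sprintf("specimen_%04d", seq_along(unmatched))

  ## global uniqueness across plates
  if (anyDuplicated(out$label)) {
    dup <- ave(seq_along(out$label), out$label, FUN = seq_along)
    out$label[dup > 1] <- sprintf("%s_dup%d", out$label[dup > 1],
                                  dup[dup > 1] - 1L)
  }
  out
}
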