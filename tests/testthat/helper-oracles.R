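# Independent brute-force oracles used to cross-check the package's compiled
# implementations, plus small fixture builders. All pure R, written against
# the definitions rather than the package internals.

# connectivity offsets as an n x 3 matrix of (dz, dy, dx)
oracleOffsets <- function(connectivity) {
  o <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  a <- rowSums(abs(o))
  keep <- switch(as.character(connectivity),
                 "6" = a == 1,
                 "18" = a >= 1 & a <= 2,
                 "26" = a >= 1)
  o[keep, , drop = FALSE]
}

# exhaustive breadth-first flood fill; ids in raster order (slices, then
# rows, then columns) of each component's first voxel
floodFillOracle <- function(mask, connectivity) {
  d <- dim(mask)
  labels <- array(0L, d)
  off <- oracleOffsets(connectivity)
  nextId <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!mask[z, y, x] || labels[z, y, x] > 0L) next
    nextId <- nextId + 1L
    queue <- matrix(c(z, y, x), 1)
    labels[z, y, x] <- nextId
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(off))) {
        p <- cur + off[k, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && labels[p[1], p[2], p[3]] == 0L) {
          labels[p[1], p[2], p[3]] <- nextId
          queue <- rbind(queue, p)
        }
      }
    }
  }
  labels
}

# a voxel is surface iff it is foreground and any face/edge/corner neighbour
# (or out-of-volume position) is background
surfaceVoxelOracle <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  off <- oracleOffsets(26)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!mask[z, y, x]) next
    for (k in seq_len(nrow(off))) {
      p <- c(z, y, x) + off[k, ]
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        out[z, y, x] <- TRUE
        break
      }
    }
  }
  out
}

# 1D run-length oracle for plate detection over a per-slice count sequence
plateSpanOracle <- function(counts, minSize) {
  spans <- NULL
  start <- NA
  for (i in seq_along(counts)) {
    occ <- counts[i] >= minSize
    if (occ && is.na(start)) start <- i
    if ((!occ || i == length(counts)) && !is.na(start)) {
      end <- if (occ) i else i - 1L
      spans <- rbind(spans, c(start, end))
      start <- NA
    }
  }
  if (is.null(spans))
    return(data.frame(startSlice = integer(0), endSlice = integer(0),
                      centreSlice = numeric(0)))
  data.frame(startSlice = spans[, 1], endSlice = spans[, 2],
             centreSlice = (spans[, 1] + spans[, 2]) / 2)
}

# read an exported slice folder back as an integer (z, y, x) array
readStack <- function(dir) {
  fs <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  sl <- lapply(fs, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  })
  arr <- array(0L, c(length(sl), dim(sl[[1]])))
  for (z in seq_along(sl)) arr[z, , ] <- sl[[z]]
  arr
}

# digital sphere mask of radius r voxels
sphereMask <- function(r, n = 2 * r + 5) {
  cen <- (n + 1) / 2
  g <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  array((g$z - cen)^2 + (g$y - cen)^2 + (g$x - cen)^2 <= r^2, c(n, n, n))
}

# small single-plate phantom for fast tests
tinyPhantom <- function(seed = 1, ...) {
  generatePhantom(phantomConfig(nPlates = 1, gridRows = 2, gridCols = 3,
                                seed = seed, ...))
}

# segmentation settings used throughout the phantom tests: cel base 6,
# bracket lower 52, matching a mount level of 31 and a specimen level of 114
segmentPhantom <- function(ph, minBlobSize = 20) {
  mask <- bracketThreshold(celShade(ph$volume, 6), 52, 255)
  list(mask = mask,
       blobs = labelBlobs(mask, 26, minBlobSize),
       spans = detectPlates(mask, minBlobSize))
}

# pair each blob with its nearest truth specimen and report the fraction of
# assignments whose label equals that specimen's recorded label
truthAccuracy <- function(blobs, assignments, truth) {
  tab <- blobTable(blobs)
  hits <- vapply(seq_len(nrow(assignments)), function(i) {
    b <- tab[tab$id == assignments$blobId[i], ]
    j <- which.min((truth$cz - b$cz)^2 + (truth$cy - b$cy)^2 +
                     (truth$cx - b$cx)^2)
    identical(assignments$label[i], truth$label[j])
  }, logical(1))
  mean(hits)
}
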