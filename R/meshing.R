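## Point clouds and surface meshes from binary masks; PLY read/write.

emptyMeshCondition <- function(msg = "nothing to mesh: mask has no foreground") {
  structure(class = c("plateCT_empty_mesh", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

## logical array of surface voxels: foreground with any background (or
## out-of-volume) neighbour. method "slice": 4-neighbourhood within each z
## slice; method "3d": full 26-neighbourhood.
surfaceVoxels <- function(arr, method = c("slice", "3d")) {
  method <- match.arg(method)
  d <- dim(arr)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  offs <- if (method == "slice")
    list(c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  else {
    o <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    o <- o[rowSums(abs(o)) > 0, ]
    lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
  }
  anyBg <- array(FALSE, d)
  zi <- 2:(d[1] + 1); yi <- 2:(d[2] + 1); xi <- 2:(d[3] + 1)
  for (o in offs)
    anyBg <- anyBg | !pad[zi + o[1], yi + o[2], xi + o[3], drop = FALSE]
  arr & anyBg
}

#' Point cloud from a binary mask
#'
#' Filled: one point per foreground voxel. Hollow: only boundary voxels of
#' the foreground are retained — including the boundaries of internal voids,
#' so models keep internal surfaces — which cuts memory for meshing and
#' viewing. The default hollowing is the full 26-neighbourhood 3D
#' morphological boundary (a voxel is kept iff any face/edge/corner
#' neighbour is background); \code{method = "slice"} instead detects edges
#' slice by slice with the 2D 4-neighbourhood, which additionally drops
#' voxels only exposed in z.
#'
#' @param mask a [VoxelMask-class] or logical 3D array.
#' @param hollow keep only surface voxels?
#' @param method hollowing neighbourhood: \code{"3d"} (default) or
#'   \code{"slice"}.
#' @return list with \code{points} (n x 3 integer matrix of 1-based
#'   \code{(z, y, x)} voxel indices) and \code{hollow}; an empty mask yields
#'   zero points.
#' @examples
#' blk <- array(TRUE, c(3, 3, 3))
#' nrow(maskToPointCloud(blk)$points)               # 27
#' nrow(maskToPointCloud(blk, hollow = TRUE)$points) # 26 (centre dropped)
#' @export
maskToPointCloud <- function(mask, hollow = FALSE,
                             method = c("3d", "slice")) {
  method <- match.arg(method)
  arr <- if (is(mask, "VoxelMask")) mask@data else mask
  if (hollow) arr <- surfaceVoxels(arr, method)
  pts <- which(arr, arr.ind = TRUE)
  colnames(pts) <- c("z", "y", "x")
  list(points = pts, hollow = isTRUE(hollow))
}

#' Extract an iso-surface mesh from a binary mask
#'
#' Extracts the level-0.5 surface of the binary field as a triangle mesh in
#' the marching-cubes family, with no smoothing, so the exported surface
#' preserves the segmentation exactly (at the cost of a blocky texture). The
#' mask is padded with one background voxel on all sides first, so specimens
#' touching the volume border still yield closed surfaces. Cells are
#' processed on a consistent tetrahedral subdivision, which makes the output
#' provably watertight (every edge shared by exactly two faces) — a property
#' the downstream mesh-volume and 3D-printing uses rely on.
#'
#' @param mask a [VoxelMask-class] or logical/integer 3D array.
#' @param level iso-level; fixed at 0.5 for binary masks.
#' @return a [SurfaceMesh-class] in voxel units, vertices in the source
#'   volume's continuous frame (voxel i centred at i - 0.5).
#' @section Errors: a mask with no foreground raises a condition of class
#'   \code{plateCT_empty_mesh} ("nothing to mesh").
#' @export
marchingCubes <- function(mask, level = 0.5) {
  arr <- if (is(mask, "VoxelMask")) mask@data else mask
  stopifnot(length(dim(arr)) == 3)
  if (!any(arr != 0)) stop(emptyMeshCondition())
  d <- dim(arr)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.integer(arr > level)
  res <- cpp_march_tets(as.integer(pad), dim(pad))
  v <- res$vertices
  ## lattice coords -> continuous frame of the unpadded mask:
  ## padded 0-based node i corresponds to unpadded voxel centre i - 0.5
  v <- v - 0.5
  colnames(v) <- c("x", "y", "z")
  SurfaceMesh(v, res$faces, units = "voxel")
}

#' Re-centre a mesh and convert it to real units
#'
#' Meshes inherit the coordinates of the larger source volume, so they are
#' offset from the origin; this translates the vertex centroid to (0, 0, 0)
#' and multiplies all coordinates by \code{voxelSizeUm / 1000}, converting
#' the arbitrary voxel integers into millimetres.
#'
#' @param mesh a [SurfaceMesh-class] in voxel units.
#' @param voxelSizeUm voxel edge length in microns (> 0).
#' @return the mesh in mm, centred on the origin.
#' @export
recentreAndScale <- function(mesh, voxelSizeUm) {
  if (!is.numeric(voxelSizeUm) || voxelSizeUm <= 0)
    stop("voxelSizeUm must be positive")
  v <- mesh@vertices
  v <- sweep(v, 2, colMeans(v))
  v <- v * (voxelSizeUm / 1000)
  SurfaceMesh(v, mesh@faces, units = "mm",
              comments = unique(c(mesh@comments,
                                  sprintf("voxel_size_um %g", voxelSizeUm),
                                  "units mm")))
}

#' Enclosed volume of a closed mesh
#'
#' Signed sum of origin tetrahedra over the faces; exact for watertight,
#' consistently oriented meshes.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return enclosed volume, in cubic mesh units.
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(a * cr) / 6)
}

#' Is a mesh watertight?
#'
#' @param mesh a [SurfaceMesh-class].
#' @return \code{TRUE} iff every undirected edge is incident to exactly two
#'   faces.
#' @export
meshIsWatertight <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Connected components of a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @return number of vertex-connected components.
#' @export
meshComponents <- function(mesh) {
  n <- nrow(mesh@vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh@faces
  for (i in seq_len(nrow(f))) {
    a <- find(f[i, 1]); b <- find(f[i, 2]); cc <- find(f[i, 3])
    parent[b] <- a; parent[cc] <- a
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Write a mesh as PLY
#'
#' Stanford polygon format: element \code{vertex} with float32 x/y/z
#' properties, element \code{face} with a uchar-counted uint32 vertex-index
#' list. Binary little-endian by default; \code{ascii = TRUE} for a
#' plain-text file. Comment lines carry the specimen label, voxel size and
#' units. A read-back round trip reproduces vertices to float32 precision and
#' faces exactly.
#'
#' @param mesh a non-empty [SurfaceMesh-class].
#' @param path output file.
#' @param ascii write the ASCII dialect instead of binary little-endian.
#' @return invisibly, \code{path}.
#' @export
writePLY <- function(mesh, path, ascii = FALSE) {
  if (nrow(mesh@vertices) == 0 || nrow(mesh@faces) == 0)
    stop(emptyMeshCondition("nothing to mesh: empty mesh cannot be written"))
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  header <- c(
    "ply",
    if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
    paste("comment", c("generated by plateCT", mesh@comments,
                       sprintf("units %s", mesh@units))),
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nf),
    "property list uchar uint vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  v <- t(mesh@vertices)
  f0 <- mesh@faces - 1L
  if (ascii) {
    vtxt <- apply(t(v), 1, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " "))
    ftxt <- apply(f0, 1, function(r) paste(c(3, r), collapse = " "))
    writeLines(c(vtxt, ftxt), con, sep = "\n")
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Reads the dialect written by [writePLY()] (ASCII or binary little-endian,
#' float32 vertex x/y/z, uchar-counted integer face lists); tolerant of extra
#' comment lines.
#'
#' @param path the PLY file.
#' @return a [SurfaceMesh-class]; units recovered from a
#'   \code{comment units ...} line if present, else \code{"voxel"}.
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readHeaderLine(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 1000) stop("malformed PLY header")
  }
  fmt <- sub("^format ", "", grep("^format ", header, value = TRUE)[1])
  ascii <- startsWith(fmt, "ascii")
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", header, value = TRUE)[1]))
  units <- "voxel"
  uc <- grep("^comment units ", header, value = TRUE)
  if (length(uc)) units <- sub("^comment units ", "", uc[length(uc)])
  comments <- sub("^comment ", "", grep("^comment ", header, value = TRUE))

  if (ascii) {
    lines <- readLines(con, warn = FALSE)
    lines <- lines[nzchar(lines)]
    v <- do.call(rbind, lapply(lines[seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
    f <- do.call(rbind, lapply(lines[nv + seq_len(nf)], function(l) {
      x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      stopifnot(x[1] == 3)
      x[2:4] + 1L
    }))
  } else {
    v <- matrix(readBin(con, "numeric", n = 3 * nv, size = 4,
                        endian = "little"), ncol = 3, byrow = TRUE)
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3) stop("only triangular faces are supported")
      f[i, ] <- readBin(con, "integer", n = 3, size = 4,
                        endian = "little") + 1L
    }
  }
  SurfaceMesh(v, f, units = if (units %in% c("voxel", "mm")) units
                            else "voxel",
              comments = comments)
}

## read a newline-terminated header line from a binary connection
readHeaderLine <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop("unexpected end of PLY header")
    if (b == as.raw(10)) break
    chars <- c(chars, b)
  }
  sub("\r$", "", rawToChar(chars))
}
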