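## Synthetic stacked-plate phantom: mount slabs with well cavities, ellipsoidal
## specimens, partial-volume blur and additive noise, plus full ground truth.

#' Phantom configuration
#'
#' Parameters of the synthetic stacked-microtiter-plate volume generated by
#' [generatePhantom()]. Defaults emulate a 24-well (4 x 6) plate format,
#' two plates stacked in z, and the three-peak greyscale structure of a real
#' bulk scan: air ~0, plastic mount ~31, bone/specimen ~114 on the 8-bit
#' scale. Gaussian blur before noise reproduces the partial-volume "halo" at
#' specimen margins.
#'
#' @param nPlates number of stacked plates.
#' @param gridRows,gridCols well array dimensions per plate.
#' @param wellPitch voxels between adjacent well centres.
#' @param specimenRadiusRange (min, max) base radius of the ellipsoidal
#'   specimens, voxels.
#' @param greyAir,greyMount,greySpecimen 8-bit levels of the three materials;
#'   must satisfy \code{0 <= air < mount < specimen <= 255}.
#' @param blurSigma Gaussian blur sigma in voxels (0 disables).
#' @param noiseSigma additive Gaussian noise sigma in grey levels, truncated
#'   at 3 sigma (0 disables).
#' @param gapSlices empty slices between (and before/after) plates.
#' @param plateSlices slab thickness of one plate, slices.
#' @param margin voxels of air between the well array and the volume edge.
#' @param occupancy per-well probability a specimen is present, in [0, 1].
#' @param doubledWell optional \code{c(plate, row, col)} (1-based): that well
#'   receives two specimens (the "damage during transfer" case).
#' @param emptyWell optional \code{c(plate, row, col)}: that well is left
#'   empty regardless of occupancy, and its CSV cell blank.
#' @param seed integer RNG seed; the phantom is bit-identical for a fixed
#'   configuration.
#' @param voxelSize voxel edge length recorded in the metadata, microns.
#' @return a \code{PhantomConfig} (list).
#' @export
phantomConfig <- function(nPlates = 2, gridRows = 4, gridCols = 6,
                          wellPitch = 16, specimenRadiusRange = c(4, 6),
                          greyAir = 0, greyMount = 31, greySpecimen = 114,
                          blurSigma = 0.8, noiseSigma = 3,
                          gapSlices = 8, plateSlices = 14, margin = 4,
                          occupancy = 1, doubledWell = NULL, emptyWell = NULL,
                          seed = 1, voxelSize = 48) {
  cfg <- list(nPlates = as.integer(nPlates), gridRows = as.integer(gridRows),
              gridCols = as.integer(gridCols), wellPitch = wellPitch,
              specimenRadiusRange = specimenRadiusRange,
              greyAir = greyAir, greyMount = greyMount,
              greySpecimen = greySpecimen, blurSigma = blurSigma,
              noiseSigma = noiseSigma, gapSlices = as.integer(gapSlices),
              plateSlices = as.integer(plateSlices), margin = margin,
              occupancy = occupancy, doubledWell = doubledWell,
              emptyWell = emptyWell, seed = as.integer(seed),
              voxelSize = voxelSize)
  stopifnot(cfg$nPlates >= 1, cfg$gridRows >= 1, cfg$gridCols >= 1,
            cfg$occupancy >= 0, cfg$occupancy <= 1,
            0 <= cfg$greyAir, cfg$greyAir < cfg$greyMount,
            cfg$greyMount < cfg$greySpecimen, cfg$greySpecimen <= 255,
            cfg$specimenRadiusRange[1] <= cfg$specimenRadiusRange[2])
  if (cfg$specimenRadiusRange[2] * 2 + 2 > cfg$wellPitch)
    stop("specimens cannot fit: max diameter + clearance exceeds well pitch")
  class(cfg) <- "PhantomConfig"
  cfg
}

## separable 3D Gaussian blur; edge-renormalised kernel
gaussBlur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blurAxis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      keep <- j >= 1 & j <= n
      K[i, j[keep]] <- k[keep] / sum(k[keep])
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(a, perm)
    m <- matrix(a, n)
    a <- array(K %*% m, dim = d[perm])
    aperm(a, order(perm))
  }
  for (ax in 1:3) arr <- blurAxis(arr, ax)
  arr
}

#' Generate a synthetic stacked-plate phantom with ground truth
#'
#' Builds a 3D volume of \code{nPlates} mount-greyscale slabs separated by
#' empty z-gaps; each slab carries a \code{gridRows x gridCols} array of
#' cylindrical well cavities, and each occupied well contains a randomly
#' oriented ellipsoidal specimen at specimen greyscale, jittered off the well
#' centre. Gaussian blur is applied before clipped additive Gaussian noise,
#' so object margins carry a smooth partial-volume halo. All placements are
#' recorded as ground truth, with matching per-plate CSV label sheets.
#'
#' @param cfg a [phantomConfig()].
#' @return a list with elements:
#' \describe{
#'   \item{volume}{the [CTVolume-class] (8-bit).}
#'   \item{truth}{list: \code{specimens} (data.frame with plate, row, col,
#'     centroid \code{cz,cy,cx}, \code{voxelCount}, \code{label}),
#'     \code{spans} (data.frame of the specimen z-extent per plate),
#'     \code{slabs} (data.frame of the mount slab z-extent per plate),
#'     \code{grids} (list of [LabelGrid-class], one per plate, with the true
#'     placing transform), \code{csvTexts} (the CSV sheet text per plate).}
#' }
#' @details Specimen labels are \code{P<plate><rowLetter><col>}, e.g.
#'   \code{P1A1}. In doubled-well mode the two co-resident specimens share the
#'   well's cell label in the CSV; their truth labels carry \code{#a}/\code{#b}
#'   markers since which suffix they receive at assignment depends on
#'   distance. Centroids are reported in continuous coordinates (voxel i
#'   centred at i - 0.5).
#' @examples
#' ph <- generatePhantom(phantomConfig(nPlates = 1, gridRows = 2, gridCols = 2,
#'                                     seed = 7))
#' nrow(ph$truth$specimens)
#' @export
generatePhantom <- function(cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  ## localise RNG state
  if (exists(".Random.seed", envir = globalenv())) {
    oldseed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldseed, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = FALSE)
  set.seed(cfg$seed)

  pitch <- cfg$wellPitch
  nx <- as.integer(cfg$gridCols * pitch + 2 * cfg$margin)
  ny <- as.integer(cfg$gridRows * pitch + 2 * cfg$margin)
  nz <- as.integer(cfg$nPlates * cfg$plateSlices +
                     (cfg$nPlates + 1) * cfg$gapSlices)
  vol <- array(as.numeric(cfg$greyAir), c(nz, ny, nx))

  ## continuous coordinate of voxel index i is i - 0.5 (frame [0, n])
  xc <- seq_len(nx) - 0.5
  yc <- seq_len(ny) - 0.5
  wellRadius <- 0.42 * pitch
  floorSlices <- 2L

  slabs <- data.frame(plateIndex = integer(0), z0 = integer(0),
                      z1 = integer(0))
  specs <- list()
  grids <- list()
  csvTexts <- character(cfg$nPlates)

  for (p in seq_len(cfg$nPlates)) {
    z0 <- cfg$gapSlices * p + cfg$plateSlices * (p - 1) + 1L
    z1 <- z0 + cfg$plateSlices - 1L
    slabs <- rbind(slabs, data.frame(plateIndex = p, z0 = z0, z1 = z1))
    vol[z0:z1, , ] <- cfg$greyMount

    cells <- matrix(NA_character_, cfg$gridRows, cfg$gridCols)
    for (r in seq_len(cfg$gridRows)) {
      for (cc in seq_len(cfg$gridCols)) {
        wx <- cfg$margin + (cc - 0.5) * pitch
        wy <- cfg$margin + (r - 0.5) * pitch
        ## carve the well cavity (open-topped cylinder above a thin floor)
        inWell <- outer(yc, xc, function(y, x)
          (x - wx)^2 + (y - wy)^2 <= wellRadius^2)
        for (z in (z0 + floorSlices):z1)
          vol[z, , ][inWell] <- cfg$greyAir

        label <- sprintf("P%d%s%d", p, LETTERS[r], cc)
        isEmpty <- !is.null(cfg$emptyWell) &&
          all(cfg$emptyWell == c(p, r, cc))
        isDoubled <- !is.null(cfg$doubledWell) &&
          all(cfg$doubledWell == c(p, r, cc))
        present <- !isEmpty && (isDoubled || runif(1) < cfg$occupancy)
        cells[r, cc] <- if (isEmpty) NA_character_ else label
        if (!present) next

        nHere <- if (isDoubled) 2L else 1L
        ## doubled wells share one (small) jitter so the pair's separation
        ## is fixed by the diagonal offsets below
        jitShared <- runif(2, -0.5, 0.5)
        for (s in seq_len(nHere)) {
          rad <- runif(1, cfg$specimenRadiusRange[1],
                       cfg$specimenRadiusRange[2])
          axes <- rad * runif(3, 0.5, 1)
          if (isDoubled) {
            ## doubled specimens: compact and small enough that the blurred
            ## pair stays clearly apart inside one well (two blobs), yet
            ## large enough to survive the partial-volume blur
            rad <- cfg$specimenRadiusRange[1] * 0.65
            axes <- rad * runif(3, 0.9, 1)
          }
          jit <- if (isDoubled) jitShared + c(-1, 1)[s] * c(2.9, 2.9)
                 else runif(2, -1.5, 1.5)
          cx0 <- wx + jit[1]
          cy0 <- wy + jit[2]
          cz0 <- z0 + floorSlices + axes[3] + runif(1, 0, 1)
          placed <- rasteriseEllipsoid(vol, cx0, cy0, cz0, axes,
                                       cfg$greySpecimen)
          vol <- placed$vol
          lab <- label
          if (isDoubled) lab <- paste0(label, "#", letters[s])
          specs[[length(specs) + 1]] <- data.frame(
            plateIndex = p, row = r, col = cc,
            cz = placed$centroid[1], cy = placed$centroid[2],
            cx = placed$centroid[3], voxelCount = placed$count,
            zmin = placed$zrange[1], zmax = placed$zrange[2],
            label = lab, stringsAsFactors = FALSE)
        }
      }
    }
    grids[[p]] <- LabelGrid(cells,
      transform = gridTransform(translate = c(cfg$margin, cfg$margin),
                                pitch = c(pitch, pitch)),
      plateIndex = p)
    csvTexts[p] <- paste(apply(cells, 1, function(rr)
      paste(ifelse(is.na(rr), "", rr), collapse = ",")), collapse = "\n")
  }

  specimens <- if (length(specs)) do.call(rbind, specs) else
    data.frame(plateIndex = integer(0), row = integer(0), col = integer(0),
               cz = numeric(0), cy = numeric(0), cx = numeric(0),
               voxelCount = integer(0), zmin = integer(0), zmax = integer(0),
               label = character(0))

  ## truth spans: z-extent of each plate's specimen content
  spans <- do.call(rbind, lapply(seq_len(cfg$nPlates), function(p) {
    s <- specimens[specimens$plateIndex == p, ]
    if (nrow(s) == 0)
      data.frame(plateIndex = p, z0 = NA_integer_, z1 = NA_integer_)
    else
      data.frame(plateIndex = p, z0 = min(s$zmin), z1 = max(s$zmax))
  }))

  if (cfg$blurSigma > 0) vol <- gaussBlur3d(vol, cfg$blurSigma)
  if (cfg$noiseSigma > 0) {
    ## truncated at 3 sigma: keeps the additive noise bounded so material
    ## levels remain separable by construction
    noise <- rnorm(length(vol), 0, cfg$noiseSigma)
    s3 <- 3 * cfg$noiseSigma
    vol <- vol + pmin(pmax(noise, -s3), s3)
  }
  vol <- round(pmin(pmax(vol, 0), 255))
  storage.mode(vol) <- "integer"
  dim(vol) <- c(nz, ny, nx)

  volume <- CTVolume(vol, voxelSize = cfg$voxelSize, bitDepth = 8)
  list(volume = volume,
       truth = list(specimens = specimens, spans = spans, slabs = slabs,
                    grids = grids, csvTexts = csvTexts, config = cfg))
}

## paint an ellipsoid into vol (dim nz,ny,nx); axes = (ax, ay, az) semi-axes
rasteriseEllipsoid <- function(vol, cx, cy, cz, axes, grey) {
  d <- dim(vol)
  zr <- max(1L, floor(cz - axes[3])):min(d[1], ceiling(cz + axes[3] + 1))
  yr <- max(1L, floor(cy - axes[2])):min(d[2], ceiling(cy + axes[2] + 1))
  xr <- max(1L, floor(cx - axes[1])):min(d[3], ceiling(cx + axes[1] + 1))
  idx <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
  cc <- idx - 0.5  # voxel centres in continuous frame
  inside <- ((cc[, "x"] - cx) / axes[1])^2 +
    ((cc[, "y"] - cy) / axes[2])^2 +
    ((cc[, "z"] - cz) / axes[3])^2 <= 1
  sel <- idx[inside, , drop = FALSE]
  vol[sel] <- grey
  list(vol = vol,
       centroid = c(mean(sel[, "z"]), mean(sel[, "y"]), mean(sel[, "x"])) - 0.5,
       count = nrow(sel),
       zrange = range(sel[, "z"]))
}

#' Write a phantom to disk
#'
#' Writes the phantom volume as a TIFF folder with \file{.info} sidecar, the
#' per-plate CSV label sheets, and a ground-truth JSON-like text summary.
#'
#' @param ph result of [generatePhantom()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writePhantom <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  volDir <- file.path(dir, "volume")
  writeVolume(ph$volume, volDir)
  csvs <- character(length(ph$truth$csvTexts))
  for (p in seq_along(ph$truth$csvTexts)) {
    csvs[p] <- file.path(dir, sprintf("plate_%02d.csv", p))
    writeLines(ph$truth$csvTexts[p], csvs[p])
  }
  truthPath <- file.path(dir, "truth.csv")
  utils::write.csv(ph$truth$specimens, truthPath, row.names = FALSE)
  invisible(c(volume = volDir, csvs, truth = truthPath))
}
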