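## End-to-end orchestration: import -> segment -> detect plates -> label ->
## export stacks + meshes, from a single config, with logging and a manifest.

#' Build a run configuration
#'
#' Aggregates every user choice of an end-to-end run. Also constructed from a
#' YAML file by [readRunConfig()].
#'
#' @param input path to the raw file or TIFF folder (or a ready
#'   [CTVolume-class] for in-memory runs).
#' @param kind \code{"auto"}, \code{"raw"} or \code{"tiff_folder"}.
#' @param info optional path to the \file{.info} sidecar (defaults to the one
#'   inside a TIFF folder).
#' @param downsampleFactor working-template stride on import.
#' @param celBase cel-shading base C (\code{0} or \code{NULL} disables).
#' @param tLower,tUpper greyscale bracket.
#' @param minBlobSize minimum blob size, working-resolution voxels.
#' @param connectivity 6, 18 or 26.
#' @param plateCSVs character vector of per-plate CSV paths (or list of
#'   CSV texts / \code{NULL} entries), ordered bottom-to-top of the stack;
#'   \code{NULL} for numeric labelling.
#' @param transforms optional list of [gridTransform()]s, one per plate.
#' @param maxMatchDistance see [assignLabels()].
#' @param modes export modes, subset of \code{c("raw", "mask", "processed")}.
#' @param margin full-resolution crop margin, voxels.
#' @param meshes export a PLY per specimen?
#' @param hollow,asciiPLY mesh options (see [maskToPointCloud()],
#'   [writePLY()]).
#' @param outDir output directory.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(input, kind = "auto", info = NULL,
                      downsampleFactor = 1, celBase = 0,
                      tLower, tUpper = 255, minBlobSize = 1,
                      connectivity = 26, plateCSVs = NULL,
                      transforms = NULL, maxMatchDistance = NULL,
                      modes = c("raw", "mask", "processed"), margin = 2,
                      meshes = TRUE, hollow = FALSE, asciiPLY = FALSE,
                      outDir) {
  cfg <- list(input = input, kind = kind, info = info,
              downsampleFactor = as.integer(downsampleFactor),
              celBase = if (is.null(celBase)) 0L else as.integer(celBase),
              tLower = tLower, tUpper = tUpper,
              minBlobSize = as.integer(minBlobSize),
              connectivity = as.integer(connectivity),
              plateCSVs = plateCSVs, transforms = transforms,
              maxMatchDistance = maxMatchDistance,
              modes = modes, margin = margin, meshes = isTRUE(meshes),
              hollow = isTRUE(hollow), asciiPLY = isTRUE(asciiPLY),
              outDir = outDir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys match the arguments of [runConfig()], with
#'   per-plate transforms as \code{transforms: [{translate: [dx, dy],
#'   rotate_deg: ..., flip_h: ..., flip_v: ..., pitch: [px, py]}, ...]}.
#' @param ... overrides applied after reading.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  tr <- y$transforms
  if (!is.null(tr))
    tr <- lapply(tr, function(t)
      gridTransform(translate = t$translate %||% c(0, 0),
                    rotateDeg = t$rotate_deg %||% 0,
                    flipH = isTRUE(t$flip_h), flipV = isTRUE(t$flip_v),
                    pitch = t$pitch %||% c(1, 1)))
  args <- y[setdiff(names(y), "transforms")]
  args$transforms <- tr
  over <- list(...)
  args[names(over)] <- over
  do.call(runConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validateRunConfig <- function(cfg) {
  if (!is(cfg$input, "CTVolume")) {
    if (!file.exists(cfg$input))
      stop(sprintf("[validate] input '%s' does not exist", cfg$input))
    if (!is.null(cfg$info) && !file.exists(cfg$info))
      stop(sprintf("[validate] info file '%s' does not exist", cfg$info))
  }
  if (!is.null(cfg$plateCSVs) && is.character(cfg$plateCSVs)) {
    for (p in cfg$plateCSVs)
      if (!grepl("[,\n]", p) && !file.exists(p))
        stop(sprintf("[validate] label CSV '%s' does not exist", p))
  }
  if (is.null(cfg$tLower))
    stop("[validate] tLower (lower bracket threshold) is required")
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes all stages in order: import (downsampled working template),
#' optional cel-shading, bracket thresholding, 3D blobbing, plate detection,
#' label-grid loading and ID assignment, full-resolution stack export, and
#' per-specimen surface meshing. The run log (stderr and
#' \file{outDir/run.log}) records every parameter, detected plate span, the
#' corner labels of each grid for mirror verification, and all assignment
#' distances, so a run is reconstructible. A re-run into a clean directory
#' yields bit-identical outputs.
#'
#' @param cfg a [runConfig()] or path to a YAML file.
#' @return invisibly, the manifest data.frame (one row per exported
#'   specimen; failed specimens flagged in \code{status}).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "RunConfig"))
  validateRunConfig(cfg)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outDir, "run.log")
  logLines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    logLines <<- c(logLines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  say("plateCT run: downsample x%d, celBase=%d, bracket=[%s, %s], minBlobSize=%d, connectivity=%d",
      cfg$downsampleFactor, cfg$celBase, format(cfg$tLower),
      format(cfg$tUpper), cfg$minBlobSize, cfg$connectivity)

  vol <- stage("import", {
    if (is(cfg$input, "CTVolume")) {
      v <- cfg$input
      if (cfg$downsampleFactor > 1)
        v <- downsampleVolume(v, cfg$downsampleFactor)
      v
    } else {
      meta <- if (!is.null(cfg$info))
        parseInfoFile(readLines(cfg$info, warn = FALSE)) else NULL
      readVolume(cfg$input, cfg$kind, meta = meta,
                 downsampleFactor = cfg$downsampleFactor)
    }
  })
  vol <- stage("import", to8bit(vol))
  say("imported volume %s (working), %s (full)",
      paste(dim(vol), collapse = "x"),
      paste(vol@sourceDims, collapse = "x"))

  seg <- stage("segment", {
    v <- if (cfg$celBase >= 2) celShade(vol, cfg$celBase) else vol
    bracketThreshold(v, cfg$tLower, cfg$tUpper)
  })
  blobs <- stage("segment",
                 labelBlobs(seg, cfg$connectivity, cfg$minBlobSize))
  say("segmentation: %d foreground voxels, %d blobs >= %d voxels",
      sum(seg@data), nBlobs(blobs), cfg$minBlobSize)

  spans <- stage("label", detectPlates(seg, cfg$minBlobSize))
  for (i in seq_len(nrow(spans)))
    say("plate %d: slices %d-%d, centre %.1f", spans$plateIndex[i],
        spans$startSlice[i], spans$endSlice[i], spans$centreSlice[i])

  grids <- stage("label", {
    if (is.null(cfg$plateCSVs)) NULL
    else {
      g <- lapply(seq_along(cfg$plateCSVs), function(p) {
        if (is.null(cfg$plateCSVs[[p]])) return(NULL)
        grid <- loadLabelGrid(cfg$plateCSVs[[p]], plateIndex = p)
        if (!is.null(cfg$transforms))
          grid <- setGridTransform(grid, cfg$transforms[[p]])
        grid
      })
      g
    }
  })
  if (!is.null(grids)) {
    for (g in grids) {
      if (is.null(g)) next
      cl <- cornerLabels(g)
      say("plate %d corner labels (verify scan is not mirrored): %s",
          g@plateIndex, paste(names(cl), cl, sep = "=", collapse = ", "))
    }
  }

  assignments <- stage("label",
                       assignLabels(blobs, grids, spans,
                                    cfg$maxMatchDistance))
  for (i in seq_len(nrow(assignments)))
    say("blob %d -> %s (plate %d, distance %s)", assignments$blobId[i],
        assignments$label[i], assignments$plateIndex[i],
        ifelse(is.na(assignments$distance[i]), "NA",
               sprintf("%.2f", assignments$distance[i])))

  manifest <- stage("export",
                    exportSpecimens(vol, blobs, assignments,
                                    modes = cfg$modes, outDir = cfg$outDir,
                                    margin = cfg$margin))

  if (cfg$meshes) {
    f <- blobs@downsampleFactor
    for (i in seq_len(nrow(manifest))) {
      res <- tryCatch({
        a <- assignments[i, ]
        bboxFull <- unlist(manifest[i, c("z0", "z1", "y0", "y1", "x0", "x1")])
        m <- upscaleBlobMask(blobs@labels, a$blobId, bboxFull, f)
        mesh <- marchingCubes(m)
        mesh@comments <- c(sprintf("label %s", a$label))
        mesh <- recentreAndScale(mesh, voxelSize(vol))
        writePLY(mesh, file.path(cfg$outDir, manifest$dir[i],
                                 paste0(manifest$dir[i], ".ply")),
                 ascii = cfg$asciiPLY)
        "ok"
      }, error = function(e) paste("mesh failed:", conditionMessage(e)))
      if (!identical(res, "ok")) {
        manifest$status[i] <- res
        say("specimen %s: %s", manifest$label[i], res)
      }
    }
    utils::write.csv(manifest, file.path(cfg$outDir, "manifest.csv"),
                     row.names = FALSE)
  }

  say("run complete: %d specimens exported to %s", nrow(manifest),
      cfg$outDir)
  writeLines(logLines, logPath)
  invisible(manifest)
}

#' Split a stacked scan into per-plate TIFF stacks
#'
#' For memory-constrained machines: writes each detected plate's
#' full-resolution z-range as its own 8-bit TIFF folder with \file{.info}
#' sidecar, so plates can then be processed one at a time.
#'
#' @param vol the [CTVolume-class] (working template; source is re-read at
#'   full resolution).
#' @param spans plate spans from [detectPlates()] on the working mask.
#' @param outDir output directory; one subfolder per plate.
#' @param gapMargin extra full-resolution slices kept either side of each
#'   plate.
#' @return invisibly, the per-plate folder paths.
#' @export
splitPlates <- function(vol, spans, outDir, gapMargin = 2) {
  if (vol@meta@bitDepth != 8L) vol <- to8bit(vol)
  f <- vol@meta@downsampleFactor
  fd <- vol@sourceDims
  dirs <- character(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    z0 <- max(1L, (spans$startSlice[i] - 1L) * f + 1L - gapMargin)
    z1 <- min(fd[1], spans$endSlice[i] * f + gapMargin)
    crop <- readSourceCrop(vol, c(z0 = z0, z1 = z1, y0 = 1L, y1 = fd[2],
                                  x0 = 1L, x1 = fd[3]))
    pv <- CTVolume(crop, voxelSize = voxelSize(vol), bitDepth = 8)
    dirs[i] <- file.path(outDir, sprintf("plate_%02d", spans$plateIndex[i]))
    writeVolume(pv, dirs[i])
  }
  invisible(dirs)
}
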