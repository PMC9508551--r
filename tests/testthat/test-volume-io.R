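test_that("info files parse, take defaults, and round-trip exactly", {
  m <- parseInfoFile("voxel_size_um=48\ndims=1869,3191,3191\nbit_depth=8")
  expect_equal(voxelSize(m), 48)
  expect_equal(m@dims, c(1869L, 3191L, 3191L))
  expect_equal(bitDepth(m), 8L)
  expect_equal(downsampleFactor(m), 1L)  # default when key absent

  m2 <- parseInfoFile("voxel_size_um=95\ndims=10,64,64\nbit_depth=8")
  expect_equal(voxelSize(m2), 95)

  # unknown keys from vendor files are tolerated
  expect_no_error(parseInfoFile("voxel_size_um=48\nscanner=XT H 225\nkV=120"))

  for (meta in list(VolumeMeta(48, c(10, 64, 64), 8),
                    VolumeMeta(95, c(5, 32, 32), 8),
                    VolumeMeta(48, c(7, 9, 11), 16, downsampleFactor = 4))) {
    back <- parseInfoFile(writeInfoFile(meta))
    expect_equal(back@voxelSize, meta@voxelSize)
    expect_equal(back@dims, meta@dims)
    expect_equal(back@bitDepth, meta@bitDepth)
    expect_equal(back@downsampleFactor, meta@downsampleFactor)
  }
})

test_that("missing voxel size raises a recoverable metadata-absent signal", {
  expect_error(parseInfoFile(""), class = "plateCT_metadata_absent")
  expect_error(parseInfoFile("dims=5,5,5"), class = "plateCT_metadata_absent")
  # the caller can supply the value and regenerate the sidecar
  got <- tryCatch(parseInfoFile(""),
                  plateCT_metadata_absent = function(e) VolumeMeta(48))
  expect_s4_class(got, "VolumeMeta")
})

test_that("raw and TIFF-folder routes read the same phantom voxelwise", {
  ph <- tinyPhantom(seed = 11)
  td <- withr::local_tempdir()
  tiffDir <- file.path(td, "tiffs")
  writeVolume(ph$volume, tiffDir)

  # same voxels as raw (voxel-major, x fastest)
  rawPath <- file.path(td, "vol.raw")
  arr <- voxelData(ph$volume)
  writeBin(as.integer(aperm(arr, c(3, 2, 1))), rawPath, size = 1)

  vt <- readVolume(tiffDir, "tiff_folder")
  vr <- readVolume(rawPath, "raw",
                   meta = VolumeMeta(48, dim(arr), 8))
  expect_identical(voxelData(vt), arr)        # TIFF round trip voxel-exact
  expect_identical(voxelData(vr), voxelData(vt))
  expect_equal(dim(vt), dim(arr))

  # downsampled read records the factor and floors the dims
  v2 <- readVolume(tiffDir, "tiff_folder", downsampleFactor = 2)
  expect_equal(dim(v2), dim(arr) %/% 2L)
  expect_equal(downsampleFactor(v2), 2L)
  expect_equal(v2@sourceDims, dim(arr))
})

test_that("corrupt inputs fail loudly, naming the offender", {
  td <- withr::local_tempdir()
  writeBin(as.raw(1:10), file.path(td, "short.raw"))
  expect_error(
    readVolume(file.path(td, "short.raw"), "raw",
               meta = VolumeMeta(48, c(5, 5, 5), 8)),
    "short.raw.*125|125.*short.raw")

  dir.create(file.path(td, "ragged"))
  tiff::writeTIFF(matrix(0, 4, 4), file.path(td, "ragged", "s1.tif"),
                  bits.per.sample = 8)
  tiff::writeTIFF(matrix(0, 4, 5), file.path(td, "ragged", "s2.tif"),
                  bits.per.sample = 8)
  expect_error(readVolume(file.path(td, "ragged"), "tiff_folder",
                          meta = VolumeMeta(48)),
               "s2\\.tif")
})

test_that("TIFF slices stack in natural filename order", {
  td <- withr::local_tempdir()
  # write slices 1, 2, 10 with values equal to their index
  for (i in c(1, 2, 10))
    tiff::writeTIFF(matrix(i / 255, 3, 3), file.path(td, sprintf("s%d.tif", i)),
                    bits.per.sample = 8)
  v <- readVolume(td, "tiff_folder", meta = VolumeMeta(48))
  expect_equal(voxelData(v)[, 1, 1], c(1L, 2L, 10L))  # not 1, 10, 2
})

test_that("stride downsampling matches index arithmetic and composes", {
  d <- c(7, 9, 11)
  ramp <- array(seq_len(prod(d)), d)
  v <- CTVolume(ramp %% 251L, voxelSize = 10)

  expect_identical(voxelData(downsampleVolume(v, 1)), voxelData(v))

  v2 <- downsampleVolume(v, 2)
  idx <- lapply(d, function(n) (seq_len(n %/% 2) - 1L) * 2L + 1L)
  expect_identical(voxelData(v2),
                   voxelData(v)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  expect_equal(dim(v2), d %/% 2L)

  # constant volume stays constant under any factor
  cv <- CTVolume(array(7L, d), voxelSize = 10)
  expect_true(all(voxelData(downsampleVolume(cv, 3)) == 7L))

  # composition: stride a then b equals stride a*b
  v6a <- downsampleVolume(downsampleVolume(v, 2), 3)
  v6b <- downsampleVolume(v, 6)
  expect_identical(voxelData(v6a), voxelData(v6b))
  expect_equal(downsampleFactor(v6a), 6L)

  expect_error(downsampleVolume(v, 50), "exceeds")
})

test_that("to8bit is the per-voxel min-max closed form, monotone, and a
          passthrough for 8-bit input", {
  d <- c(4, 5, 5)
  ramp16 <- array(as.integer(round(seq(0, 65535, length.out = prod(d)))), d)
  v16 <- CTVolume(ramp16, voxelSize = 10, bitDepth = 16)
  out <- to8bit(v16)
  expected <- as.integer(round(255 * (as.numeric(ramp16) - min(ramp16)) /
                                 diff(range(ramp16))))
  expect_identical(as.vector(voxelData(out)), expected)
  expect_equal(range(voxelData(out)), c(0L, 255L))  # endpoints map to 0/255
  expect_equal(bitDepth(out), 8L)

  # monotone: sorted input stays sorted
  expect_false(is.unsorted(as.vector(voxelData(out))))

  v8 <- CTVolume(array(5L, d), voxelSize = 10, bitDepth = 8)
  expect_identical(voxelData(to8bit(v8)), voxelData(v8))

  const <- to8bit(CTVolume(array(999L, d), voxelSize = 10, bitDepth = 16))
  expect_true(all(voxelData(const) == 0L))
})

test_that("full-resolution source re-crop matches the in-memory data", {
  ph <- tinyPhantom(seed = 12)
  td <- withr::local_tempdir()
  writeVolume(ph$volume, file.path(td, "v"))
  full <- voxelData(ph$volume)

  for (kind in c("tiff", "raw")) {
    vol <- if (kind == "tiff") {
      readVolume(file.path(td, "v"), "tiff_folder", downsampleFactor = 2)
    } else {
      rawPath <- file.path(td, "v.raw")
      writeBin(as.integer(aperm(full, c(3, 2, 1))), rawPath, size = 1)
      readVolume(rawPath, "raw", meta = VolumeMeta(48, dim(full), 8),
                 downsampleFactor = 2)
    }
    bbox <- c(z0 = 3L, z1 = 9L, y0 = 5L, y1 = 20L, x0 = 2L, x1 = 30L)
    crop <- readSourceCrop(vol, bbox)
    expect_identical(crop, full[3:9, 5:20, 2:30])
  }
})
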