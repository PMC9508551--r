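test_that("cel-shading quantises downward to multiples of the base", {
  expect_equal(celShade(114, 10), 110)
  expect_equal(celShade(52, 6), 48)     # the bulk-scan validation settings
  x <- 0:255
  for (C in c(2, 6, 10, 17)) {
    y <- celShade(x, C)
    expect_true(all(y %% C == 0))
    expect_true(all(y <= x & x < y + C))
    expect_identical(celShade(y, C), y)         # idempotent
    expect_true(all(diff(y) >= 0))              # never reorders greys
  }
  v <- CTVolume(array(c(0L, 31L, 114L, 255L), c(1, 2, 2)), voxelSize = 48)
  expect_equal(as.vector(voxelData(celShade(v, 10))), c(0L, 30L, 110L, 250L))
  expect_error(celShade(v, 1), "base")
})

test_that("grey-level count conventions: floor and enumeration", {
  expect_equal(celShadeLevels(255, 10), 25)
  expect_equal(celShadeLevels(255, 10, "enumerate"), 26)
  # conventions agree exactly when the base divides the scale
  expect_equal(celShadeLevels(255, 5), 51)
  expect_equal(celShadeLevels(255, 5, "enumerate"), 52)
  expect_equal(celShadeLevels(256, 2, "enumerate"),
               celShadeLevels(256, 2) + 1)
})

test_that("bracket thresholding keeps exactly the voxels inside the bracket", {
  vals <- c(0, 31, 52, 114, 255)
  expect_equal(bracketThreshold(vals, 52, 255), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(bracketThreshold(vals, 52, 200), c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_true(all(bracketThreshold(0:255, 0, 255)))
  expect_error(bracketThreshold(vals, 100, 50), "tLower")

  v <- CTVolume(array(as.integer(vals[c(1:5, 5:1, 1, 3)]), c(3, 2, 2)),
                voxelSize = 48)
  m <- bracketThreshold(v, 52, 255)
  expect_s4_class(m, "VoxelMask")
  expect_identical(dim(m), dim(v))
})

test_that("thresholding after cel-shading is unchanged for bin-aligned brackets", {
  set.seed(31)
  x <- sample(0:255, 4000, replace = TRUE)
  for (C in c(5, 10)) {
    lo <- 5 * C; hi <- 20 * C - 1  # [lo, hi] covers whole bins of width C
    expect_identical(bracketThreshold(celShade(x, C), lo, hi),
                     bracketThreshold(x, lo, hi))
  }
})

test_that("blob labelling finds components, sizes, centroids and the filter", {
  arr <- array(FALSE, c(10, 12, 14))
  arr[2:4, 2:4, 2:4] <- TRUE
  arr[6:8, 8:10, 10:12] <- TRUE
  b <- labelBlobs(arr, 26, 1)
  tab <- blobTable(b)
  expect_equal(nBlobs(b), 2L)
  expect_equal(tab$voxelCount, c(27L, 27L))
  # centroids at the cube centres, continuous frame (voxel i centred i - 0.5)
  expect_equal(unlist(tab[1, c("cz", "cy", "cx")]),
               c(cz = 2.5, cy = 2.5, cx = 2.5))
  expect_equal(unlist(tab[2, c("cz", "cy", "cx")]),
               c(cz = 6.5, cy = 8.5, cx = 10.5))
  expect_equal(unlist(tab[1, c("z0", "z1", "y0", "y1", "x0", "x1")]),
               c(z0 = 2, z1 = 4, y0 = 2, y1 = 4, x0 = 2, x1 = 4))

  # an isolated voxel is removed by the min-size filter
  arr2 <- arr
  arr2[10, 1, 1] <- TRUE
  expect_equal(nBlobs(labelBlobs(arr2, 26, 2)), 2L)
  expect_equal(nBlobs(labelBlobs(arr2, 26, 1)), 3L)

  # empty mask: empty table, not an error
  expect_equal(nBlobs(labelBlobs(array(FALSE, c(3, 3, 3)), 26, 1)), 0L)
})

test_that("blob ids follow raster order of each component's first voxel", {
  arr <- array(FALSE, c(4, 4, 4))
  arr[3, 1, 1] <- TRUE   # later slice: must get the higher id
  arr[1, 4, 4] <- TRUE
  tab <- blobTable(labelBlobs(arr, 6, 1))
  expect_equal(tab$z0, c(1L, 3L))
})

test_that("labelling matches the exhaustive flood-fill oracle on random masks", {
  set.seed(99)
  for (rep in 1:12) {
    conn <- sample(c(6, 18, 26), 1)
    mask <- array(stats::runif(8^3) < 0.35, c(8, 8, 8))
    got <- voxelData(labelBlobs(mask, conn, 1))
    expect_identical(got, floodFillOracle(mask, conn),
                     info = sprintf("rep %d conn %d", rep, conn))
  }
})

test_that("voxel conservation and connectivity monotonicity hold", {
  set.seed(7)
  for (rep in 1:5) {
    mask <- array(stats::runif(10^3) < 0.3, c(10, 10, 10))
    b <- labelBlobs(mask, 26, 1)
    expect_equal(sum(blobTable(b)$voxelCount), sum(mask))
    n26 <- nBlobs(b)
    n6 <- nBlobs(labelBlobs(mask, 6, 1))
    expect_lte(n26, n6)
  }
})

test_that("pipeline segmentation recovers every phantom specimen", {
  ph <- generatePhantom(phantomConfig(seed = 21))
  seg <- segmentPhantom(ph)
  expect_equal(nBlobs(seg$blobs), nrow(ph$truth$specimens))
})

test_that("blobMask extracts a single blob, optionally cropped", {
  arr <- array(FALSE, c(5, 5, 5))
  arr[1:2, 1:2, 1:2] <- TRUE
  arr[4:5, 4:5, 4:5] <- TRUE
  b <- labelBlobs(arr, 26, 1)
  m1 <- blobMask(b, 1)
  expect_equal(sum(voxelData(m1)), 8)
  expect_identical(dim(m1), dim(arr))
  m2 <- blobMask(b, 2, crop = TRUE)
  expect_identical(dim(m2), c(2L, 2L, 2L))
  expect_true(all(voxelData(m2)))
  expect_error(blobMask(b, 9), "no blob")
})
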