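test_that("filled point clouds conserve voxel count; hollow is a subset", {
  blk <- array(TRUE, c(2, 2, 2))
  expect_equal(nrow(maskToPointCloud(blk)$points), 8L)

  blk3 <- array(TRUE, c(3, 3, 3))
  pcF <- maskToPointCloud(blk3)
  pcH <- maskToPointCloud(blk3, hollow = TRUE)
  expect_equal(nrow(pcF$points), 27L)
  expect_equal(nrow(pcH$points), 26L)   # all but the centre voxel
  # and the dropped voxel is indeed the centre
  expect_false(any(pcH$points[, 1] == 2 & pcH$points[, 2] == 2 &
                     pcH$points[, 3] == 2))
  # hollow subset of filled
  keyF <- apply(pcF$points, 1, paste, collapse = ",")
  keyH <- apply(pcH$points, 1, paste, collapse = ",")
  expect_true(all(keyH %in% keyF))

  # empty mask -> empty cloud, not an error
  expect_equal(nrow(maskToPointCloud(array(FALSE, c(2, 2, 2)))$points), 0L)
})

test_that("hollow clouds retain internal cavity surfaces", {
  a <- array(TRUE, c(5, 5, 5))
  a[3, 3, 3] <- FALSE  # one-voxel internal void
  # 3d boundary: all six face-neighbours of the cavity are retained
  pts <- maskToPointCloud(a, hollow = TRUE, method = "3d")$points
  for (d in list(c(2, 3, 3), c(4, 3, 3), c(3, 2, 3), c(3, 4, 3),
                 c(3, 3, 2), c(3, 3, 4)))
    expect_true(any(pts[, 1] == d[1] & pts[, 2] == d[2] & pts[, 3] == d[3]))
  # per-slice edge detection sees the cavity's in-plane neighbours
  ptsS <- maskToPointCloud(a, hollow = TRUE, method = "slice")$points
  for (d in list(c(3, 2, 3), c(3, 4, 3), c(3, 3, 2), c(3, 3, 4)))
    expect_true(any(ptsS[, 1] == d[1] & ptsS[, 2] == d[2] &
                      ptsS[, 3] == d[3]))
})

test_that("3d hollowing matches the brute-force surface-voxel oracle", {
  set.seed(55)
  for (rep in 1:8) {
    mask <- array(stats::runif(12^3) < 0.5, c(12, 12, 12))
    got <- maskToPointCloud(mask, hollow = TRUE, method = "3d")$points
    want <- which(surfaceVoxelOracle(mask), arr.ind = TRUE)
    expect_equal(unname(got), unname(want))
  }
})

test_that("iso-surfaces are closed, component-correct and volume-faithful", {
  # smallest case: a single voxel gives a closed mesh
  m1 <- marchingCubes(array(TRUE, c(1, 1, 1)))
  expect_true(meshIsWatertight(m1))
  expect_equal(meshComponents(m1), 1L)
  # its bounding box spans exactly one voxel per axis
  expect_equal(unname(apply(meshVertices(m1), 2, function(v) diff(range(v)))),
               c(1, 1, 1))

  # two disjoint cubes -> two components
  a <- array(FALSE, c(8, 8, 12))
  a[2:4, 2:4, 2:4] <- TRUE
  a[5:7, 5:7, 8:10] <- TRUE
  m2 <- marchingCubes(a)
  expect_equal(meshComponents(m2), 2L)
  expect_true(meshIsWatertight(m2))

  # digital sphere: enclosed mesh volume within 5% of the voxel count
  sph <- sphereMask(10)
  ms <- marchingCubes(sph)
  expect_true(meshIsWatertight(ms))
  expect_lt(abs(meshVolume(ms) - sum(sph)) / sum(sph), 0.05)

  # nothing to mesh is a typed signal
  expect_error(marchingCubes(array(FALSE, c(3, 3, 3))),
               class = "plateCT_empty_mesh")
})

test_that("meshes stay watertight on random small phantom masks", {
  set.seed(77)
  for (rep in 1:25) {
    mask <- array(stats::runif(9^3) < runif(1, 0.2, 0.6), c(9, 9, 9))
    if (!any(mask)) next
    m <- marchingCubes(mask)
    expect_true(meshIsWatertight(m), info = sprintf("rep %d", rep))
  }
})

test_that("meshes touching the volume border still close", {
  a <- array(TRUE, c(2, 3, 4))  # fills the whole volume
  m <- marchingCubes(a)
  expect_true(meshIsWatertight(m))
  expect_equal(meshComponents(m), 1L)
})

test_that("recentre-and-scale zeroes the centroid and converts to mm", {
  sph <- sphereMask(6)
  m <- marchingCubes(sph)
  mm <- recentreAndScale(m, 48)
  expect_equal(mm@units, "mm")
  expect_lt(max(abs(colMeans(meshVertices(mm)))), 1e-9)

  # unit cube at 48 um -> 0.048 mm bounding box
  cube <- recentreAndScale(marchingCubes(array(TRUE, c(1, 1, 1))), 48)
  expect_equal(unname(apply(meshVertices(cube), 2,
                            function(v) diff(range(v)))),
               rep(0.048, 3))

  # voxel size 1000 um: coordinates unchanged except centring
  m1000 <- recentreAndScale(m, 1000)
  cen <- sweep(meshVertices(m), 2, colMeans(meshVertices(m)))
  expect_equal(meshVertices(m1000), cen, ignore_attr = TRUE)

  # volume scales with the cube of the linear factor
  expect_equal(meshVolume(recentreAndScale(m, 2000)),
               meshVolume(m) * 8, tolerance = 1e-9)

  expect_error(recentreAndScale(m, 0), "positive")
  expect_error(recentreAndScale(m, -48), "positive")
})

test_that("PLY write/read round trips vertices (float32) and faces exactly", {
  td <- withr::local_tempdir()
  tet <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                     rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  for (ascii in c(TRUE, FALSE)) {
    p <- file.path(td, sprintf("tet_%d.ply", ascii))
    writePLY(tet, p, ascii = ascii)
    back <- readPLY(p)
    expect_equal(meshVertices(back), meshVertices(tet), ignore_attr = TRUE)
    expect_identical(meshFaces(back), meshFaces(tet))
  }

  # ASCII and binary dialects parse to the same mesh for a real surface
  sph <- recentreAndScale(marchingCubes(sphereMask(5)), 48)
  pa <- file.path(td, "s_ascii.ply"); pb <- file.path(td, "s_bin.ply")
  writePLY(sph, pa, ascii = TRUE)
  writePLY(sph, pb, ascii = FALSE)
  ma <- readPLY(pa); mb <- readPLY(pb)
  expect_identical(meshFaces(ma), meshFaces(mb))
  expect_equal(meshVertices(ma), meshVertices(mb), tolerance = 1e-6)
  expect_equal(ma@units, "mm")
  # float32 precision bound on the binary route
  expect_lt(max(abs(meshVertices(mb) - meshVertices(sph))), 1e-6)

  # empty mesh is refused with the typed signal
  empty <- SurfaceMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(writePLY(empty, file.path(td, "e.ply")),
               class = "plateCT_empty_mesh")
})
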