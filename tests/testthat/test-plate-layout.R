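test_that("plate spans follow the stated occupancy rule", {
  sp <- plateSpansFromCounts(c(0, 0, 5, 9, 8, 0, 0, 7, 7, 0), 3)
  expect_equal(sp$startSlice, c(3L, 8L))
  expect_equal(sp$endSlice, c(5L, 9L))
  expect_equal(sp$centreSlice, c(4, 8.5))
  expect_equal(sp$plateIndex, 1:2)

  # all slices occupied -> one span covering everything
  sp2 <- plateSpansFromCounts(rep(10, 6), 3)
  expect_equal(nrow(sp2), 1L)
  expect_equal(c(sp2$startSlice, sp2$endSlice), c(1L, 6L))

  # nothing occupied -> empty, not an error
  expect_equal(nrow(plateSpansFromCounts(c(0, 1, 2), 5)), 0L)
})

test_that("plate detection matches the 1D run-length oracle on random counts", {
  set.seed(17)
  for (rep in 1:50) {
    counts <- stats::rpois(sample(5:40, 1), lambda = sample(1:6, 1))
    minSize <- sample(1:5, 1)
    got <- plateSpansFromCounts(counts, minSize)
    want <- plateSpanOracle(counts, minSize)
    expect_equal(got$startSlice, want$startSlice)
    expect_equal(got$endSlice, want$endSlice)
    expect_equal(got$centreSlice, want$centreSlice)
  }
})

test_that("detectPlates on the phantom finds each plate's specimen z-range", {
  ph <- generatePhantom(phantomConfig(seed = 14, nPlates = 3, gapSlices = 8))
  seg <- segmentPhantom(ph)
  expect_equal(nrow(seg$spans), 3L)
  for (i in 1:3) {
    # the detected span sits inside the plate slab and covers the specimen
    # bulk; the outermost cap slices can fall under the per-slice pixel
    # minimum (and are further thinned by the partial-volume blur)
    truthSpan <- ph$truth$spans[i, ]
    slab <- ph$truth$slabs[i, ]
    expect_gte(seg$spans$startSlice[i], slab$z0)
    expect_lte(seg$spans$endSlice[i], slab$z1)
    expect_lte(seg$spans$startSlice[i], truthSpan$z0 + 2)
    expect_gte(seg$spans$endSlice[i], truthSpan$z1 - 2)
    # spans ordered and non-overlapping
    if (i > 1) expect_gt(seg$spans$startSlice[i], seg$spans$endSlice[i - 1])
  }
})

test_that("label grids load from CSV with empty cells; errors are loud", {
  g <- loadLabelGrid("A1,A2,A3\nB1,B2,B3")
  expect_equal(dim(g@cells), c(2L, 3L))
  expect_false(anyNA(g@cells))

  g2 <- loadLabelGrid("A1,,A3\nB1,B2,B3")
  expect_true(is.na(g2@cells[1, 2]))
  expect_equal(sum(is.na(g2@cells)), 1L)

  expect_error(loadLabelGrid("A1,A2\nB1,B2,B3"), "row 2")
  expect_error(loadLabelGrid("A1,A2\nA1,B2"), "duplicate")

  # default transform: unit pitch, no rotation/flip/translation
  expect_equal(g@transform$pitch, c(1, 1))
  expect_equal(g@transform$rotateDeg, 0)
  expect_false(g@transform$flipH || g@transform$flipV)
})

test_that("cell centres obey the closed form and transform order", {
  g <- LabelGrid(matrix(paste0("s", 1:6), 2, 3, byrow = TRUE),
                 transform = gridTransform(pitch = c(10, 10)))
  cen <- cellCentres(g)
  first <- cen[cen$row == 1 & cen$col == 1, ]
  expect_equal(c(first$x, first$y), c(5, 5))

  # rotating 180 degrees maps cell (1,1) onto the untransformed (R,C) centre
  g180 <- setGridTransform(g, gridTransform(rotateDeg = 180, pitch = c(10, 10)))
  cen180 <- cellCentres(g180)
  a <- cen180[cen180$row == 1 & cen180$col == 1, ]
  b <- cen[cen$row == 2 & cen$col == 3, ]
  expect_equal(c(a$x, a$y), c(b$x, b$y))

  # flip_h swaps the x of (r, 1) and (r, C)
  gh <- setGridTransform(g, gridTransform(flipH = TRUE, pitch = c(10, 10)))
  cenh <- cellCentres(gh)
  expect_equal(cenh$x[cenh$row == 1 & cenh$col == 1],
               cen$x[cen$row == 1 & cen$col == 3])
  expect_equal(cenh$y, cen$y)

  # translation is applied last
  gt <- setGridTransform(g, gridTransform(translate = c(100, -3),
                                          rotateDeg = 180, pitch = c(10, 10)))
  cent <- cellCentres(gt)
  expect_equal(cent$x, cellCentres(g180)$x + 100)
  expect_equal(cent$y, cellCentres(g180)$y - 3)
})

test_that("corner labels surface the flip state for mirror checks", {
  g <- LabelGrid(matrix(c("A1", "A2", "A3", "B1", "B2", "B3"), 2, 3,
                        byrow = TRUE))
  expect_equal(unname(cornerLabels(g)), c("A1", "A3", "B1", "B3"))
  gh <- setGridTransform(g, gridTransform(flipH = TRUE))
  expect_equal(unname(cornerLabels(gh)), c("A3", "A1", "B3", "B1"))
  g1 <- LabelGrid(matrix("only", 1, 1))
  expect_equal(unname(cornerLabels(g1)), rep("only", 4))
})

test_that("phantom blobs receive exactly their truth labels", {
  ph <- generatePhantom(phantomConfig(seed = 22))
  seg <- segmentPhantom(ph)
  asn <- assignLabels(seg$blobs, ph$truth$grids, seg$spans)
  expect_equal(nrow(asn), 48L)
  expect_equal(truthAccuracy(seg$blobs, asn, ph$truth$specimens), 1)
  expect_false(anyDuplicated(asn$label) > 0)
})

test_that("assignment survives grid translation error up to 0.4 pitch", {
  ph <- generatePhantom(phantomConfig(seed = 23))
  seg <- segmentPhantom(ph)
  pitch <- ph$truth$config$wellPitch
  for (frac in c(0.2, 0.4)) {
    grids <- lapply(ph$truth$grids, function(g) {
      tr <- g@transform
      tr$translate <- tr$translate + frac * pitch * c(1, -1) / sqrt(2)
      setGridTransform(g, tr)
    })
    asn <- assignLabels(seg$blobs, grids, seg$spans,
                        maxMatchDistance = 0.75 * pitch)
    expect_equal(truthAccuracy(seg$blobs, asn, ph$truth$specimens), 1,
                 info = sprintf("translation %.1f pitch", frac))
  }
})

test_that("assignment is invariant under a common rigid transform", {
  ph <- tinyPhantom(seed = 24)
  seg <- segmentPhantom(ph)
  asn0 <- assignLabels(seg$blobs, ph$truth$grids, seg$spans)

  # translate both the grid and the blob centroids by the same offset
  shift <- c(12.5, -7.25)
  tab <- blobTable(seg$blobs)
  tab$cx <- tab$cx + shift[1]
  tab$cy <- tab$cy + shift[2]
  grids <- lapply(ph$truth$grids, function(g) {
    tr <- g@transform
    tr$translate <- tr$translate + shift
    setGridTransform(g, tr)
  })
  asn1 <- assignLabels(tab, grids, seg$spans)
  expect_equal(asn1$label, asn0$label)
  expect_equal(asn1$distance, asn0$distance)
})

test_that("empty wells get no blob and doubled wells get suffixed labels", {
  ph <- generatePhantom(phantomConfig(seed = 25, doubledWell = c(1, 2, 3),
                                      emptyWell = c(2, 1, 1)))
  seg <- segmentPhantom(ph)
  asn <- assignLabels(seg$blobs, ph$truth$grids, seg$spans)
  # 24 + 24 wells, one doubled (+1), one empty (-1)
  expect_equal(nrow(asn), 48L)
  expect_false("P2A1" %in% asn$label)
  expect_setequal(grep("^P1B3", asn$label, value = TRUE),
                  c("P1B3_1", "P1B3_2"))
  # the closer blob takes the _1 suffix
  d1 <- asn$distance[asn$label == "P1B3_1"]
  d2 <- asn$distance[asn$label == "P1B3_2"]
  expect_lte(d1, d2)
})

test_that("no grid means sequential numeric labels; far blobs fall back too", {
  ph <- tinyPhantom(seed = 26)
  seg <- segmentPhantom(ph)
  asn <- assignLabels(seg$blobs, NULL, seg$spans)
  expect_equal(asn$label, sprintf("specimen_%04d", seq_len(nrow(asn))))

  # a grid placed far away: everything degrades to numeric labels
  grids <- lapply(ph$truth$grids, function(g) {
    tr <- g@transform
    tr$translate <- tr$translate + c(1e5, 1e5)
    setGridTransform(g, tr)
  })
  asn2 <- assignLabels(seg$blobs, grids, seg$spans)
  expect_true(all(grepl("^specimen_", asn2$label)))

  # grid/span count mismatch is a hard error
  expect_error(assignLabels(seg$blobs, list(), seg$spans), "grids")
})
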