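test_that("block grids tile the volume exactly", {
  g <- blockGrid(c(1000L, 1000L, 1000L), 512L, 64L)
  expect_equal(nrow(g@blocks), 8L)
  expect_equal(nrow(blockGrid(c(512L, 512L, 512L), 512L)@blocks), 1L)
  g1 <- blockGrid(c(512L, 512L, 512L), 512L, 64L)
  expect_equal(unname(unlist(g1@blocks[1, -1])),
               c(0L, 511L, 0L, 511L, 0L, 511L, 0L, 511L, 0L, 511L, 0L, 511L))
  g2 <- blockGrid(c(513L, 1L, 1L), 512L)
  expect_equal(nrow(g2@blocks), 2L)
  expect_equal(g2@blocks$core_zmax, c(511L, 512L))
  expect_error(blockGrid(c(10L, 10L, 10L), 0L), "positive")

  # cores tile exactly and pads contain cores
  g3 <- blockGrid(c(70L, 50L, 33L), 32L, 8L)
  cover <- array(0L, c(70, 50, 33))
  for (i in seq_len(nrow(g3@blocks))) {
    b <- g3@blocks[i, ]
    cover[(b$core_zmin:b$core_zmax) + 1, (b$core_ymin:b$core_ymax) + 1,
          (b$core_xmin:b$core_xmax) + 1] <-
      cover[(b$core_zmin:b$core_zmax) + 1, (b$core_ymin:b$core_ymax) + 1,
            (b$core_xmin:b$core_xmax) + 1] + 1L
    expect_true(b$pad_zmin <= b$core_zmin && b$pad_zmax >= b$core_zmax)
  }
  expect_true(all(cover == 1L))
})

test_that("nonempty-block selection matches a per-block scan", {
  g <- blockGrid(c(64L, 64L, 64L), 32L, 8L)
  empty <- BinaryMask(array(FALSE, c(64, 64, 64)))
  expect_length(nonemptyBlocks(g, empty), 0L)
  one <- array(FALSE, c(64, 64, 64))
  one[40, 10, 10] <- TRUE
  expect_length(nonemptyBlocks(g, BinaryMask(one)), 1L)
  set.seed(71)
  m <- array(runif(64^3) < 0.001, c(64, 64, 64))
  keep <- nonemptyBlocks(g, BinaryMask(m))
  ref <- integer(0)
  for (i in seq_len(nrow(g@blocks))) {
    b <- g@blocks[i, ]
    if (any(m[(b$core_zmin:b$core_zmax) + 1, (b$core_ymin:b$core_ymax) + 1,
              (b$core_xmin:b$core_xmax) + 1]))
      ref <- c(ref, i)
  }
  expect_equal(keep, ref)
})

test_that("blockwise components equal the global labeling", {
  set.seed(73)
  grid <- blockGrid(c(64L, 64L, 64L), 32L, 8L)
  for (i in 1:6) {
    m <- BinaryMask(array(runif(64^3) < 0.15, c(64, 64, 64)))
    for (conn in c(6L, 18L, 26L)) {
      expect_identical(voxelData(blockwiseComponents(m, grid, conn)),
                       voxelData(connectedComponents(m, conn)))
    }
  }
  # a rod crossing several blocks is one component
  rod <- array(FALSE, c(64, 64, 64))
  rod[32, 32, ] <- TRUE
  expect_equal(nLabels(blockwiseComponents(BinaryMask(rod), grid, 26L)), 1L)
})

test_that("blockwise detection merges instances once and only once", {
  fx <- cachedFixture("puncta96", function() punctaFixture())
  grid1 <- blockGrid(c(96L, 96L, 96L), 96L, 0L)   # degenerate single block
  d1 <- blockwiseDetectSites(fx$volume, probabilityProvider("scaled_intensity"),
                             segmentationProfile("presynaptic"), grid1)
  d0 <- detectSites(fx$volume)
  expect_identical(voxelData(d1$labels), voxelData(d0$labels))
  expect_equal(d1$sites, d0$sites)

  grid2 <- blockGrid(c(96L, 96L, 96L), 32L, 24L)
  d2 <- suppressWarnings(blockwiseDetectSites(
    fx$volume, probabilityProvider("scaled_intensity"),
    segmentationProfile("presynaptic"), grid2))
  expect_identical(voxelData(d2$labels), voxelData(d0$labels))
})

test_that("blocked and unblocked workflow runs agree", {
  d <- cachedFixture("smallPhantom", function() generatePhantom(
    smallPhantomSpec()))
  ch <- w2Channels(d)
  r0 <- runWorkflow(2, ch)
  grid <- blockGrid(c(128L, 128L, 128L), 64L, 32L)
  r1 <- suppressWarnings(blockwiseDetectAndConnect(ch, grid = grid,
                                                   kind = 2L))
  expect_identical(workflowSummary(r0), workflowSummary(r1))
  expect_identical(voxelData(r0@labels$presyn), voxelData(r1@labels$presyn))
  expect_equal(connectionTable(r0), connectionTable(r1))
})
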