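test_that("connected components respect the chosen adjacency", {
  empty <- BinaryMask(array(FALSE, c(4, 4, 4)))
  expect_equal(nLabels(connectedComponents(empty)), 0L)

  # two in-plane diagonal voxels: joined at 18/26, split at 6
  m <- array(FALSE, c(1, 4, 4))
  m[1, 2, 2] <- TRUE
  m[1, 3, 3] <- TRUE
  bm <- BinaryMask(m)
  expect_equal(nLabels(connectedComponents(bm, 26)), 1L)
  expect_equal(nLabels(connectedComponents(bm, 18)), 1L)
  expect_equal(nLabels(connectedComponents(bm, 6)), 2L)

  # full-diagonal voxels: joined only at 26
  m2 <- array(FALSE, c(4, 4, 4))
  m2[2, 2, 2] <- TRUE
  m2[3, 3, 3] <- TRUE
  expect_equal(nLabels(connectedComponents(BinaryMask(m2), 26)), 1L)
  expect_equal(nLabels(connectedComponents(BinaryMask(m2), 18)), 2L)
})

test_that("components agree with a label-propagation oracle on random masks", {
  set.seed(13)
  for (i in 1:8) {
    m <- array(runif(20^3) < 0.2, c(20, 20, 20))
    for (conn in c(6L, 18L, 26L)) {
      got <- voxelData(connectedComponents(BinaryMask(m), conn))
      ref <- propagationComponents(m, conn)
      expect_identical(got, ref)   # both label by raster-first voxel
    }
  }
})

test_that("size filter keeps the boundary size and relabels densely", {
  # components of sizes 100, 399, 400, 5000 -> two survive a 400 gate
  d <- c(12, 30, 120)
  a <- array(FALSE, d)
  a[1:10, 1:10, 1] <- TRUE                     # 100
  a[1:10, 1:10, 5:8] <- TRUE; a[10, 10, 8] <- FALSE  # 399
  a[1:10, 1:10, 12:15] <- TRUE                 # 400
  a[1:10, 1:25, 20:39] <- TRUE                 # 5000
  lab <- connectedComponents(BinaryMask(a), 26)
  expect_equal(nLabels(lab), 4L)
  counts <- tabulate(voxelData(lab))
  expect_setequal(counts, c(100L, 399L, 400L, 5000L))
  filt <- sizeFilter(lab, 400L)
  expect_equal(nLabels(filt), 2L)
  expect_setequal(tabulate(voxelData(filt)), c(400L, 5000L))

  # min 1 is the identity partition; the filter is idempotent
  expect_identical(partitionSignature(voxelData(sizeFilter(lab, 1L))),
                   partitionSignature(voxelData(lab)))
  expect_identical(voxelData(sizeFilter(filt, 400L)), voxelData(filt))

  # random labels: survivors equal a per-label histogram count
  set.seed(17)
  m <- array(runif(16^3) < 0.25, c(16, 16, 16))
  lab <- connectedComponents(BinaryMask(m), 6)
  for (minV in c(2L, 5L, 10L)) {
    keepRef <- which(tabulate(voxelData(lab)) >= minV)
    got <- sizeFilter(lab, minV)
    expect_equal(nLabels(got), length(keepRef))
    expect_identical(sort(unique(voxelData(lab)[voxelData(got) > 0])),
                     keepRef)
  }
})

test_that("closeUnitGaps closes single-voxel gaps and is idempotent", {
  m <- array(FALSE, c(3, 3, 5))
  m[1, 1, 1] <- TRUE
  m[1, 1, 3] <- TRUE
  cl <- closeUnitGaps(BinaryMask(m))
  expect_true(voxelData(cl)[1, 1, 2])
  expect_equal(nLabels(connectedComponents(cl, 26)), 1L)
  expect_true(all(voxelData(cl)[m]))   # never removes foreground

  cube <- BinaryMask(array(TRUE, c(4, 4, 4)))
  expect_identical(voxelData(closeUnitGaps(cube)), voxelData(cube))

  iso <- array(FALSE, c(7, 7, 7))
  iso[4, 4, 4] <- TRUE
  expect_identical(voxelData(closeUnitGaps(BinaryMask(iso))), iso)

  set.seed(23)
  r <- BinaryMask(array(runif(12^3) < 0.1, c(12, 12, 12)))
  once <- closeUnitGaps(r)
  twice <- closeUnitGaps(once)
  expect_identical(voxelData(once), voxelData(twice))
})
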