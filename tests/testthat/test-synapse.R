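test_that("scaled_intensity provider matches the closed-form rescale", {
  v <- VoxelVolume(array(c(0L, 255L), c(2, 1, 1)))
  p <- probabilityMap(v, probabilityProvider("scaled_intensity", lo = 0,
                                             hi = 255))
  expect_equal(as.vector(voxelData(p)), c(0, 1))

  flat <- VoxelVolume(array(7L, c(3, 3, 3)))
  expect_true(all(voxelData(probabilityMap(flat)) == 0))

  set.seed(51)
  a <- array(sample.int(256, 6^3, TRUE) - 1L, c(6, 6, 6))
  p <- probabilityMap(VoxelVolume(a),
                      probabilityProvider("scaled_intensity", lo = 10,
                                          hi = 200))
  expect_equal(voxelData(p), array(pmin(pmax((a - 10) / 190, 0), 1), dim(a)))

  expect_error(probabilityMap(flat, probabilityProvider("nope")),
               "scaled_intensity")
})

test_that("external_model provider wraps a callable and checks shape", {
  v <- VoxelVolume(array(runif(4^3), c(4, 4, 4)))
  p <- probabilityMap(v, probabilityProvider("external_model",
                                             fun = function(a) a * 0 + 0.5))
  expect_true(all(voxelData(p) == 0.5))
  expect_error(probabilityMap(v, probabilityProvider("external_model")),
               "fun")
})

test_that("watershed partitions the foreground exactly", {
  # single sphere: one instance, voxel set preserved
  m <- stampSphere(array(FALSE, c(16, 16, 16)), c(8, 8, 8), 5)
  lab <- watershedInstances(BinaryMask(m))
  expect_equal(nLabels(lab), 1L)
  expect_identical(voxelData(lab) > 0L, m)

  # overlapping dumbbell: two instances whose union is the foreground
  m2 <- stampSphere(array(FALSE, c(24, 24, 32)), c(12, 12, 12), 5)
  m2 <- stampSphere(m2, c(12, 12, 20), 5)
  lab2 <- watershedInstances(BinaryMask(m2))
  expect_equal(nLabels(lab2), 2L)
  expect_identical(voxelData(lab2) > 0L, m2)

  expect_equal(nLabels(watershedInstances(
    BinaryMask(array(FALSE, c(4, 4, 4))))), 0L)

  # random blobs: always an exact partition
  set.seed(53)
  for (i in 1:5) {
    m <- array(FALSE, c(24, 24, 24))
    for (j in 1:5) m <- stampSphere(m, sample(5:20, 3, TRUE), sample(2:4, 1))
    lab <- watershedInstances(BinaryMask(m))
    expect_identical(voxelData(lab) > 0L, m)
  }
})

test_that("detectSites finds true sites and gates out specks", {
  fx <- cachedFixture("puncta96", function() punctaFixture())
  det <- detectSites(fx$volume)
  expect_equal(nrow(det$sites), fx$nSites)
  expect_true(all(det$sites$voxel_count >= 400L))
  # centroids within a voxel of ground truth
  gtTab <- SynConnect:::.siteTable(fx$gt)
  mm <- matchInstances(det$labels, fx$gt)
  expect_equal(nrow(mm), fx$nSites)
  for (r in seq_len(nrow(mm))) {
    dz <- det$sites$centroid_z[mm$pred_id[r]] - gtTab$centroid_z[mm$gt_id[r]]
    dy <- det$sites$centroid_y[mm$pred_id[r]] - gtTab$centroid_y[mm$gt_id[r]]
    dx <- det$sites$centroid_x[mm$pred_id[r]] - gtTab$centroid_x[mm$gt_id[r]]
    expect_lt(sqrt(dz^2 + dy^2 + dx^2), 1)
  }

  # a postsynaptic profile keeps small sites the presynaptic gate removes
  fx2 <- punctaFixture(d = c(64L, 64L, 64L), nSites = 5L, nSpecks = 0L,
                       siteSize = c(250L, 390L), seed = 101L)
  expect_equal(nrow(detectSites(fx2$volume)$sites), 0L)
  expect_equal(nrow(detectSites(
    fx2$volume, profile = segmentationProfile("postsynaptic"))$sites), 5L)

  # empty input, no sites
  expect_equal(nrow(detectSites(VoxelVolume(array(0L, c(8, 8, 8))))$sites),
               0L)
})

test_that("detection is equivariant under translation", {
  fx <- punctaFixture(d = c(64L, 64L, 64L), nSites = 4L, nSpecks = 5L,
                      siteSize = c(450L, 900L), seed = 103L)
  shift <- c(3L, 5L, 2L)
  shifted <- VoxelVolume(SynConnect:::.translateArray(voxelData(fx$volume),
                                                      shift))
  d0 <- detectSites(fx$volume)$sites
  d1 <- detectSites(shifted)$sites
  expect_equal(nrow(d0), nrow(d1))
  ord0 <- order(d0$centroid_z, d0$centroid_y, d0$centroid_x)
  ord1 <- order(d1$centroid_z, d1$centroid_y, d1$centroid_x)
  expect_equal(d1$centroid_z[ord1], d0$centroid_z[ord0] + shift[1])
  expect_equal(d1$centroid_y[ord1], d0$centroid_y[ord0] + shift[2])
  expect_equal(d1$centroid_x[ord1], d0$centroid_x[ord0] + shift[3])
  expect_equal(d1$voxel_count[ord1], d0$voxel_count[ord0])
})

test_that("raising thresholds never increases foreground or site counts", {
  fx <- cachedFixture("puncta96", function() punctaFixture())
  p <- probabilityMap(fx$volume)
  fg <- vapply(c(0.3, 0.5, 0.8, 0.95),
               function(t) sum(voxelData(applyThreshold(p, t))), numeric(1))
  expect_true(all(diff(fg) <= 0))
  counts <- vapply(c(100L, 400L, 700L, 1600L), function(ms) {
    nrow(detectSites(fx$volume,
                     profile = segmentationProfile("presynaptic",
                                                   minSizeVoxels = ms))$sites)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
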