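test_that("bresenham lines include both endpoints and unit steps", {
  pts <- SynConnect:::.bresenham3d(c(0L, 0L, 0L), c(0L, 0L, 15L))
  expect_equal(nrow(pts), 16L)
  expect_equal(pts[1, ], c(0L, 0L, 0L))
  expect_equal(pts[16, ], c(0L, 0L, 15L))
  pts <- SynConnect:::.bresenham3d(c(0L, 0L, 0L), c(3L, 7L, 2L))
  steps <- abs(pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])
  expect_true(all(steps <= 1L))
  expect_equal(pts[nrow(pts), ], c(3L, 7L, 2L))
})

test_that("bridging connects gaps within tolerance and leaves others", {
  # voxels 15 apart: one round draws the connecting line
  m <- array(FALSE, c(3, 3, 20))
  m[1, 1, 1] <- TRUE
  m[1, 1, 16] <- TRUE
  br <- bridgeComponents(BinaryMask(m), bridgeSpec(maxGap = 20,
                                                   iterations = 1L))
  expect_equal(nLabels(connectedComponents(br, 26)), 1L)
  expect_true(all(voxelData(br)[1, 1, 1:16]))   # the 14 intervening voxels
  expect_true(all(voxelData(br)[m]))

  # 25 apart stays apart at gap 20 even with 4 rounds
  m2 <- array(FALSE, c(3, 3, 30))
  m2[1, 1, 1] <- TRUE
  m2[1, 1, 27] <- TRUE
  br2 <- bridgeComponents(BinaryMask(m2), bridgeSpec(maxGap = 20,
                                                     iterations = 4L))
  expect_equal(nLabels(connectedComponents(br2, 26)), 2L)
})

test_that("iteration matters: a blob reachable only via a bridge joins in round 2", {
  # A(0,0,0) and C(0,0,12) are 12 apart (connect in round 1); B(0,13,6) is
  # sqrt(205) ~ 14.32 from both and connects only through the dilated
  # round-1 bridge voxel (0,1,6), at distance exactly 12
  d <- c(3, 16, 16)
  m <- array(FALSE, d)
  m[1, 1, 1] <- TRUE    # A
  m[1, 1, 13] <- TRUE   # C
  m[1, 14, 7] <- TRUE   # B
  one <- bridgeComponents(BinaryMask(m), bridgeSpec(maxGap = 12,
                                                    iterations = 1L))
  expect_equal(nLabels(connectedComponents(one, 26)), 2L)
  two <- bridgeComponents(BinaryMask(m), bridgeSpec(maxGap = 12,
                                                    iterations = 2L))
  expect_equal(nLabels(connectedComponents(two, 26)), 1L)
})

test_that("bridging is monotone and never raises the component count", {
  set.seed(41)
  for (i in 1:5) {
    m <- array(FALSE, c(20, 20, 20))
    for (j in 1:6) m <- stampSphere(m, sample(3:18, 3, TRUE), 2)
    bm <- BinaryMask(m)
    k0 <- nLabels(connectedComponents(bm, 26))
    br <- bridgeComponents(bm, bridgeSpec(maxGap = 6, iterations = 2L))
    expect_true(all(voxelData(br)[m]))
    expect_lte(nLabels(connectedComponents(br, 26)), k0)
  }
})

test_that("neuron-mask post-processing recovers tubes and drops specks", {
  # a tube with two sub-tolerance gaps plus small specks -> 1 component
  d <- c(24, 40, 160)
  a <- solidTube(d, 12, 20, 5:150, 4)         # ~7000 voxels
  a[, , 60:65] <- FALSE                        # 6-voxel gap
  a[, , 100:107] <- FALSE                      # 8-voxel gap
  set.seed(43)
  for (i in 1:20) {
    ctr <- c(sample(3:22, 1), sample(25:38, 1), sample(3:157, 1))
    a <- stampSphere(a, ctr, 2)                # ~30-voxel specks
  }
  v <- VoxelVolume(array(ifelse(a, 200L, 0L), d))
  cfg <- pipelineConfig(maskMinSize = 2000L)
  out <- postprocessNeuronMask(v, cfg)
  expect_equal(nLabels(connectedComponents(out, 26)), 1L)

  # empty volume maps to an empty mask
  expect_equal(sum(voxelData(postprocessNeuronMask(
    VoxelVolume(array(0L, c(8, 8, 8))), cfg))), 0L)

  # an over-tolerance gap leaves two components when both fragments pass
  # the size gate, and drops a fragment that does not
  b <- solidTube(d, 12, 20, c(5:60, 87:150), 4)   # 26-voxel gap
  vb <- VoxelVolume(array(ifelse(b, 200L, 0L), d))
  expect_equal(nLabels(connectedComponents(postprocessNeuronMask(vb, cfg),
                                           26)), 2L)
  small <- solidTube(d, 12, 20, c(5:24, 51:150), 4)  # fragment ~1000 < 2000
  vs <- VoxelVolume(array(ifelse(small, 200L, 0L), d))
  expect_equal(nLabels(connectedComponents(postprocessNeuronMask(vs, cfg),
                                           26)), 1L)
})
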