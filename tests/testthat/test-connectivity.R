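mk10site <- function() {
  # one 10-voxel site with exactly 5 voxels inside the mask
  lab <- array(0L, c(1, 2, 5))
  lab[1, , ] <- 1L
  mask <- array(FALSE, c(1, 2, 5))
  mask[1, 1, 1:5] <- TRUE        # covers 5 of the 10 site voxels
  list(sites = LabelVolume(lab), mask = BinaryMask(mask))
}

test_that("assignment respects the inclusive 50% rule", {
  f <- mk10site()
  a <- assignSitesToMask(f$sites, f$mask, 0.5)
  expect_equal(a$overlap_fraction, 0.5)
  expect_true(a$assigned)
  # 4 of 10 voxels -> not assigned
  m2 <- voxelData(f$mask)
  m2[1, 1, 5] <- FALSE
  a2 <- assignSitesToMask(f$sites, BinaryMask(m2), 0.5)
  expect_equal(a2$overlap_fraction, 0.4)
  expect_false(a2$assigned)
  expect_error(assignSitesToMask(f$sites,
                                 BinaryMask(array(FALSE, c(2, 2, 2)))),
               "shapes")
})

test_that("overlap fractions equal a brute-force voxel count", {
  set.seed(61)
  m <- array(runif(32^3) < 0.3, c(32, 32, 32))
  blobs <- array(FALSE, c(32, 32, 32))
  for (j in 1:6) blobs <- stampSphere(blobs, sample(5:28, 3, TRUE), 3)
  lab <- connectedComponents(BinaryMask(blobs), 26)
  a <- assignSitesToMask(lab, BinaryMask(m), 0.5)
  for (id in a$id) {
    vox <- which(voxelData(lab) == id)
    cnt <- 0L
    for (v in vox) if (m[v]) cnt <- cnt + 1L
    expect_equal(a$overlap_voxels[a$id == id], cnt)
    expect_equal(a$overlap_fraction[a$id == id], cnt / length(vox))
  }
})

test_that("site-site contacts use the inclusive 0.1% rule on the query", {
  # 1000-voxel post site overlapping a pre site in exactly 1 voxel
  post <- array(0L, c(10, 10, 10))
  post[1:10, 1:10, 1:10] <- 1L      # 1000 voxels
  pre <- array(0L, c(10, 10, 10))
  pre[1, 1, 1] <- 1L
  conns <- findSiteSiteContacts(LabelVolume(pre), LabelVolume(post))
  expect_equal(nrow(conns), 1L)
  expect_equal(conns$overlap_fraction, 0.001)
  expect_equal(conns$overlap_voxels, 1L)

  # no overlap, no dilation -> nothing
  pre0 <- array(0L, c(10, 10, 10))
  expect_equal(nrow(findSiteSiteContacts(LabelVolume(pre0),
                                         LabelVolume(post))), 0L)

  # a post site touching two pre sites emits two connections (polyadic)
  d <- c(4, 4, 12)
  post2 <- array(0L, d)
  post2[1:4, 1:4, 5:8] <- 1L
  pre2 <- array(0L, d)
  pre2[1:4, 1:4, 1:5] <- 1L        # overlaps post in plane x=5
  pre2[1:4, 1:4, 8:12] <- 2L       # overlaps post in plane x=8
  conns2 <- findSiteSiteContacts(LabelVolume(pre2), LabelVolume(post2))
  expect_equal(nrow(conns2), 2L)
  expect_setequal(conns2$pre_site_id, c(1L, 2L))
  expect_equal(unique(conns2$post_object_id), 1L)
})

test_that("site-mask contacts mirror the rule with the mask as target", {
  d <- c(8, 8, 16)
  pre <- array(0L, d)
  pre[2:6, 2:6, 2:6] <- 1L
  mask <- array(TRUE, d)
  conns <- findSiteMaskContacts(LabelVolume(pre), BinaryMask(mask))
  expect_equal(conns$overlap_fraction, 1.0)
  expect_equal(conns$post_object_type, "mask")

  # 500-voxel site, single overlap voxel: 0.002 >= 0.001
  pre2 <- array(0L, c(5, 10, 10))
  pre2[1:5, 1:10, 1:10] <- 1L
  mask2 <- array(FALSE, c(5, 10, 10))
  mask2[1, 1, 1] <- TRUE
  conns2 <- findSiteMaskContacts(LabelVolume(pre2), BinaryMask(mask2))
  expect_equal(conns2$overlap_fraction, 1 / 500)
  # disjoint -> none
  mask3 <- array(FALSE, c(5, 10, 10))
  expect_equal(nrow(findSiteMaskContacts(LabelVolume(pre2),
                                         BinaryMask(mask3))), 0L)
})

test_that("contact dilation finds apposed but non-overlapping sites", {
  d <- c(6, 6, 12)
  pre <- array(0L, d)
  pre[2:5, 2:5, 2:4] <- 1L
  post <- array(0L, d)
  post[2:5, 2:5, 5:7] <- 1L        # face-adjacent, zero shared voxels
  cfg0 <- pipelineConfig()
  expect_equal(nrow(findSiteSiteContacts(LabelVolume(pre), LabelVolume(post),
                                         cfg0)), 0L)
  cfg1 <- pipelineConfig(contactDilation = 1L)
  conns <- findSiteSiteContacts(LabelVolume(pre), LabelVolume(post), cfg1)
  expect_equal(nrow(conns), 1L)
})

test_that("workflows validate their channels and satisfy count relations", {
  expect_error(runWorkflow(2, list(presyn = VoxelVolume(array(0L, c(4, 4, 4)))
  )), "missing")
  expect_error(runWorkflow(5, list()), "kind")

  d <- cachedFixture("smallPhantom", function() generatePhantom(
    smallPhantomSpec()))
  rep <- runWorkflow(2, w2Channels(d))
  s <- workflowSummary(rep)
  expect_lte(s$presyn_sites_connected, s$connections)
  expect_gte(s$presyn_total, s$presyn_on_neuron1)
  expect_true(all(connectionTable(rep)$overlap_fraction >= 0.001))
  expect_true(all(connectionTable(rep)$overlap_fraction <= 1))

  # fractions shrink the result sets as they rise
  cfgHi <- pipelineConfig(assignmentFraction = 0.9)
  sHi <- workflowSummary(runWorkflow(2, w2Channels(d), cfgHi))
  expect_lte(sHi$presyn_on_neuron1, s$presyn_on_neuron1)

  # with the whole volume as neuron-1 mask, W2 reduces to
  # detect-everything + contact analysis
  chAll <- w2Channels(d)
  chAll$neuron1_mask <- BinaryMask(array(TRUE, dim(voxelData(d@gtPresyn))))
  sAll <- workflowSummary(runWorkflow(2, chAll))
  expect_equal(sAll$presyn_on_neuron1, sAll$presyn_total)
  expect_equal(sAll$connections, nrow(d@connections))
})

test_that("counts are invariant under label permutation and translation", {
  d <- cachedFixture("smallPhantom", function() generatePhantom(
    smallPhantomSpec()))
  cfg <- pipelineConfig()
  pre <- detectSites(d@presynChannel)$labels
  post <- detectSites(d@postsynChannel,
                      profile = segmentationProfile("postsynaptic"))$labels
  base <- findSiteSiteContacts(pre, post, cfg)
  # permute pre labels
  k <- nLabels(pre)
  perm <- c(0L, sample(seq_len(k)))
  preP <- LabelVolume(array(perm[voxelData(pre) + 1L], dim(voxelData(pre))))
  permuted <- findSiteSiteContacts(preP, post, cfg)
  expect_equal(nrow(permuted), nrow(base))
  expect_setequal(perm[base$pre_site_id + 1L], permuted$pre_site_id)
  # translate everything together
  sh <- c(2L, -3L, 4L)
  tr <- function(l) LabelVolume(SynConnect:::.translateArray(voxelData(l), sh))
  moved <- findSiteSiteContacts(tr(pre), tr(post), cfg)
  expect_equal(nrow(moved), nrow(base))
  expect_equal(sort(moved$overlap_voxels), sort(base$overlap_voxels))
})

test_that("workflows 1, 3 and 4 report the expected stages", {
  d <- cachedFixture("smallPhantom", function() generatePhantom(
    smallPhantomSpec()))
  n1 <- BinaryMask(voxelData(d@gtNeurons) == 1L)

  # W1: marker sites assigned to neuron 1
  s1 <- workflowSummary(runWorkflow(1, list(marker = d@presynChannel,
                                            neuron1_mask = n1)))
  expect_equal(s1$presyn_total, nrow(d@assignments))
  expect_equal(s1$presyn_on_neuron1,
               sum(d@assignments$neuron_id == 1L))

  # W3: assigned presynaptic sites contacting the neuron-2 mask; every
  # neuron-1 bouton is disjoint from neuron 2 by construction
  n2 <- BinaryMask(voxelData(d@gtNeurons) == 2L)
  r3 <- runWorkflow(3, list(presyn = d@presynChannel, neuron1_mask = n1,
                            neuron2_mask = n2))
  s3 <- workflowSummary(r3)
  expect_equal(s3$presyn_on_neuron1, sum(d@assignments$neuron_id == 1L))
  expect_equal(s3$connections, 0L)
  expect_true(all(connectionTable(r3)$post_object_type == "mask"))

  # W3 with neuron 1's own mask as the target: all assigned sites touch it
  s3b <- workflowSummary(runWorkflow(3, list(presyn = d@presynChannel,
                                             neuron1_mask = n1,
                                             neuron2_mask = n1)))
  expect_equal(s3b$connections, s3b$presyn_on_neuron1)

  # W4: detect-only, no assignment columns
  r4 <- runWorkflow(4, list(marker = d@presynChannel))
  expect_equal(workflowSummary(r4)$presyn_total, nrow(d@assignments))
  expect_false("assigned_mask_id" %in% names(siteTables(r4)$marker))
})
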