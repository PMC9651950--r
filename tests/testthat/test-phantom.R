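test_that("phantom generation is deterministic in the seed", {
  s <- smallPhantomSpec(seed = 5L)
  d1 <- generatePhantom(s)
  d2 <- generatePhantom(s)
  expect_identical(voxelData(d1@presynChannel), voxelData(d2@presynChannel))
  expect_identical(voxelData(d1@neuronChannel), voxelData(d2@neuronChannel))
  expect_identical(d1@connections, d2@connections)
  d3 <- generatePhantom(smallPhantomSpec(seed = 6L))
  expect_false(identical(voxelData(d1@presynChannel),
                         voxelData(d3@presynChannel)))
})

test_that("ground-truth bookkeeping matches the requested objects", {
  d <- cachedFixture("smallPhantom", function() generatePhantom(
    smallPhantomSpec()))
  s <- d@spec
  expect_equal(nrow(d@assignments), s@nNeurons * s@nPresynPerNeuron)
  expect_equal(max(voxelData(d@gtPresyn)), s@nNeurons * s@nPresynPerNeuron)
  expect_equal(nrow(d@connections), s@nPostsynApposed)
  # measured sizes within the spec ranges
  sizes <- tabulate(voxelData(d@gtPresyn))
  expect_true(all(sizes >= s@presynSizeRange[1] &
                    sizes <= s@presynSizeRange[2]))
  postSizes <- tabulate(voxelData(d@gtPostsyn))
  expect_true(all(postSizes >= s@postsynSizeRange[1] &
                    postSizes <= s@postsynSizeRange[2]))
  # apposed overlaps within the stated range
  expect_true(all(d@connections$overlap_voxels >= s@apposedOverlapRange[1] &
                    d@connections$overlap_voxels <= s@apposedOverlapRange[2]))
  validateDataset(d)
})

test_that("labeling gaps in the neuron channel stay within bridging reach", {
  d <- cachedFixture("smallPhantom", function() generatePhantom(
    smallPhantomSpec()))
  s <- d@spec
  for (k in seq_len(s@nNeurons)) {
    ch <- voxelData(d@neuronChannel)
    ch[voxelData(d@gtNeurons) != k] <- 0L
    lab <- connectedComponents(BinaryMask(ch > 0), 26)
    kcomp <- nLabels(lab)
    expect_gte(kcomp, 1L)
    if (kcomp > 1L) {
      # every fragment is within maxGap of another fragment
      dd <- dim(ch)
      surf <- which(voxelData(lab) > 0)
      co <- arrayInd(surf, dd) - 1L
      labs <- voxelData(lab)[surf]
      for (cmp in seq_len(kcomp)) {
        a <- co[labs == cmp, , drop = FALSE]
        b <- co[labs != cmp, , drop = FALSE]
        mp <- SynConnect:::.min_pair_dist(a, b)
        expect_lte(sqrt(mp$dist2), 20)
      }
    }
  }
})

test_that("corrupted datasets fail validation loudly", {
  d <- cachedFixture("smallPhantom", function() generatePhantom(
    smallPhantomSpec()))
  # shift one presynaptic site off its neuron
  bad <- d
  pre <- voxelData(bad@gtPresyn)
  neu <- voxelData(bad@gtNeurons)
  vox <- which(pre == 1L)
  neu[vox] <- 0L
  bad@gtNeurons <- LabelVolume(neu)
  expect_error(validateDataset(bad), "assignable.*1")

  # separate a connection pair
  bad2 <- d
  post <- voxelData(bad2@gtPostsyn)
  pid <- bad2@connections$post_id[1]
  pre2 <- voxelData(bad2@gtPresyn)
  post[post == pid & pre2 > 0L] <- 0L   # delete the shared voxels
  bad2@gtPostsyn <- LabelVolume(post)
  expect_error(validateDataset(bad2), "connection")
})

test_that("touching mode produces apposed but disjoint pairs", {
  d <- generatePhantom(smallPhantomSpec(seed = 9L,
                                        appositionMode = "touching"))
  ov <- SynConnect:::.overlapPairs(voxelData(d@gtPostsyn),
                                   voxelData(d@gtPresyn))
  expect_equal(nrow(ov), 0L)
  validateDataset(d)
  # with dilation the partner contacts reappear
  cfg <- pipelineConfig(contactDilation = 2L)
  conns <- findSiteSiteContacts(d@gtPresyn, d@gtPostsyn, cfg)
  expect_gte(nrow(conns), d@spec@nPostsynApposed * 0.8)
})
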