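mkLabels <- function(assign) {
  # assign: list of label -> voxel index vectors inside a 6x6x6 grid
  a <- array(0L, c(6, 6, 6))
  for (i in seq_along(assign)) a[assign[[i]]] <- i
  LabelVolume(a)
}

test_that("matching is greedy, one-to-one and deterministic", {
  set.seed(81)
  m <- array(FALSE, c(40, 24, 24))
  for (j in 1:7) m <- stampSphere(m, c(4 + 4 * j, 12, 12), 1)
  lab <- connectedComponents(BinaryMask(m), 26)
  mm <- matchInstances(lab, lab)
  expect_equal(nrow(mm), 7L)
  expect_true(all(mm$iou == 1))

  # pred overlapping two gt instances 60/40 pairs with the larger overlap
  pred <- mkLabels(list(1:100))
  gt <- mkLabels(list(1:60, 61:100))
  mm2 <- matchInstances(pred, gt, minIoU = 0.1)
  expect_equal(nrow(mm2), 1L)
  expect_equal(mm2$gt_id, 1L)
  expect_equal(mm2$overlap, 60L)

  expect_equal(nrow(matchInstances(mkLabels(list(1:10)),
                                   mkLabels(list(30:40)))), 0L)
})

test_that("precision and recall follow the confusion arithmetic", {
  mm <- data.frame(pred_id = 1:7, gt_id = 1:7, overlap = 1, iou = 1)
  pr <- precisionRecall(mm, nPred = 8, nGt = 10)
  expect_equal(pr@precision, 0.875)
  expect_equal(pr@recall, 0.7)
  expect_equal(pr@truePositives, 7L)
  expect_equal(pr@falsePositives, 1L)
  expect_equal(pr@falseNegatives, 3L)

  perfect <- precisionRecall(mm, 7, 7)
  expect_equal(perfect@precision, 1)
  expect_equal(perfect@recall, 1)
  expect_equal(precisionRecall(mm[0, ], 0, 0)@precision, 1)
  expect_error(precisionRecall(mm, 5, 7), "inconsistent")
})

test_that("metrics swap under pred/gt exchange and respect IoU monotonicity", {
  set.seed(83)
  m1 <- array(FALSE, c(24, 24, 24))
  for (j in 1:5) m1 <- stampSphere(m1, sample(4:20, 3, TRUE), 2)
  m2 <- array(FALSE, c(24, 24, 24))
  for (j in 1:4) m2 <- stampSphere(m2, sample(4:20, 3, TRUE), 2)
  p <- connectedComponents(BinaryMask(m1), 26)
  g <- connectedComponents(BinaryMask(m2), 26)
  a <- evaluateDetection(p, g)
  b <- evaluateDetection(g, p)
  expect_equal(a@precision, b@recall)
  expect_equal(a@recall, b@precision)

  tps <- vapply(c(0.05, 0.2, 0.5, 0.9), function(iou)
    nrow(matchInstances(p, g, iou)), numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("pure-noise detections reduce precision exactly", {
  fx <- cachedFixture("puncta96", function() punctaFixture())
  det <- detectSites(fx$volume)
  base <- evaluateDetection(det$labels, fx$gt)
  expect_equal(base@precision, 1)
  expect_equal(base@recall, 1)
  # add k fake detections disjoint from everything
  k <- 3L
  lab <- voxelData(det$labels)
  n0 <- nLabels(det$labels)
  lab[1:5, 1:5, 1] <- n0 + 1L
  lab[1:5, 1:5, 3] <- n0 + 2L
  lab[1:5, 1:5, 5] <- n0 + 3L
  noisy <- evaluateDetection(LabelVolume(lab), fx$gt)
  expect_equal(noisy@precision, n0 / (n0 + k))
  expect_equal(noisy@recall, 1)
})

test_that("an evaluation region restricts scoring to ground-truth areas", {
  fx <- cachedFixture("puncta96", function() punctaFixture())
  det <- detectSites(fx$volume)
  # a region that excludes everything scores trivially perfect
  reg <- BinaryMask(array(FALSE, c(96, 96, 96)))
  m0 <- evaluateDetection(det$labels, fx$gt, region = reg)
  expect_equal(m0@truePositives, 0L)
  expect_equal(m0@precision, 1)
  # full region reproduces the unrestricted result
  regAll <- BinaryMask(array(TRUE, c(96, 96, 96)))
  mAll <- evaluateDetection(det$labels, fx$gt, region = regAll)
  expect_equal(mAll@truePositives,
               evaluateDetection(det$labels, fx$gt)@truePositives)
})
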