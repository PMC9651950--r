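#' Match predicted against ground-truth instances
#'
#' Candidate pairs are all (pred, gt) label pairs with voxel overlap and
#' IoU at least `minIoU`; they are sorted by decreasing overlap voxels
#' (ties: lower pred id, then lower gt id) and accepted greedily one-to-one.
#' The matching is deterministic.  The permissive default IoU of 0.1
#' reflects that curated ground truth treats any plausibly coincident
#' cluster as the same object.
#'
#' @param pred,gt [LabelVolume-class] objects of identical shape.
#' @param minIoU minimum intersection-over-union for a candidate pair.
#' @param region optional [BinaryMask-class]; both labelings are restricted
#'   to it before matching (evaluate only where ground truth exists).
#' @return data frame `pred_id`, `gt_id`, `overlap`, `iou`, one row per
#'   accepted match.
#' @export
matchInstances <- function(pred, gt, minIoU = 0.1, region = NULL) {
  stopifnot(is(pred, "LabelVolume"), is(gt, "LabelVolume"))
  if (!identical(dim(pred@.Data), dim(gt@.Data)))
    stop("matchInstances: shapes differ", call. = FALSE)
  p <- pred@.Data
  g <- gt@.Data
  if (!is.null(region)) {
    stopifnot(is(region, "BinaryMask"))
    if (!identical(dim(region@.Data), dim(p)))
      stop("matchInstances: region shape differs", call. = FALSE)
    p <- array(ifelse(region@.Data, p, 0L), dim(p))
    g <- array(ifelse(region@.Data, g, 0L), dim(g))
  }
  empty <- data.frame(pred_id = integer(0), gt_id = integer(0),
                      overlap = integer(0), iou = numeric(0))
  kp <- max(p, 0L)
  kg <- max(g, 0L)
  if (kp == 0L || kg == 0L) return(empty)
  ov <- .overlapPairs(p, g)
  if (nrow(ov) == 0L) return(empty)
  sizeP <- tabulate(p, nbins = kp)
  sizeG <- tabulate(g, nbins = kg)
  iou <- ov$overlap / (sizeP[ov$a] + sizeG[ov$b] - ov$overlap)
  cand <- data.frame(pred_id = ov$a, gt_id = ov$b, overlap = ov$overlap,
                     iou = iou)
  cand <- cand[cand$iou >= minIoU, , drop = FALSE]
  cand <- cand[order(-cand$overlap, cand$pred_id, cand$gt_id), , drop = FALSE]
  usedP <- logical(kp)
  usedG <- logical(kg)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pi <- cand$pred_id[i]
    gi <- cand$gt_id[i]
    if (!usedP[pi] && !usedG[gi]) {
      keep[i] <- TRUE
      usedP[pi] <- TRUE
      usedG[gi] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision and recall from a match table
#'
#' `TP` is the number of accepted matches, `FP = nPred - TP`,
#' `FN = nGt - TP`; precision is `TP/(TP+FP)` (1 when no predictions) and
#' recall `TP/(TP+FN)` (1 when no ground truth).
#'
#' @param matches match table from [matchInstances()].
#' @param nPred,nGt numbers of predicted / ground-truth instances.
#' @param dice optional voxel-level Dice coefficient to carry along.
#' @return a [DetectionMetrics-class].
#' @export
precisionRecall <- function(matches, nPred, nGt, dice = NA_real_) {
  tp <- nrow(matches)
  fp <- nPred - tp
  fn <- nGt - tp
  if (fp < 0L || fn < 0L)
    stop("precisionRecall: more matches than instances - inconsistent input",
         call. = FALSE)
  new("DetectionMetrics",
      truePositives = as.integer(tp), falsePositives = as.integer(fp),
      falseNegatives = as.integer(fn),
      precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
      recall = if (tp + fn == 0L) 1 else tp / (tp + fn),
      matches = matches, dice = dice)
}

#' Evaluate a detection against ground truth
#'
#' One-to-one instance matching ([matchInstances()]) followed by
#' [precisionRecall()]; also reports the voxel-level Dice coefficient of
#' the two foregrounds as an auxiliary measure.
#'
#' @inheritParams matchInstances
#' @return a [DetectionMetrics-class].
#' @export
evaluateDetection <- function(pred, gt, minIoU = 0.1, region = NULL) {
  m <- matchInstances(pred, gt, minIoU, region)
  p <- pred@.Data > 0L
  g <- gt@.Data > 0L
  if (!is.null(region)) {
    p <- p & region@.Data
    g <- g & region@.Data
  }
  denom <- sum(p) + sum(g)
  dice <- if (denom == 0L) 1 else 2 * sum(p & g) / denom
  kp <- if (is.null(region)) nLabels(pred) else
    length(setdiff(unique(as.vector(pred@.Data[region@.Data])), 0L))
  kg <- if (is.null(region)) nLabels(gt) else
    length(setdiff(unique(as.vector(gt@.Data[region@.Data])), 0L))
  precisionRecall(m, kp, kg, dice = dice)
}

setMethod("show", "DetectionMetrics", function(object) {
  cat("DetectionMetrics\n")
  cat(sprintf("  TP %d, FP %d, FN %d\n", object@truePositives,
              object@falsePositives, object@falseNegatives))
  cat(sprintf("  precision %.4f, recall %.4f", object@precision,
              object@recall))
  if (!is.na(object@dice)) cat(sprintf(", voxel Dice %.4f", object@dice))
  cat("\n")
})
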