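# structuring-element offset builders (rows: dz, dy, dx)
.boxOffsets <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  as.matrix(g[, c("dz", "dy", "dx")])
}

.ballOffsets <- function(r) {
  g <- .boxOffsets(ceiling(r))
  g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= r^2, , drop = FALSE]
}

.dilate <- function(a, offsets) {
  storage.mode(offsets) <- "integer"
  out <- .dilate3d(as.vector(a), dim(a), offsets)
  array(out, dim(a))
}

.erode <- function(a, offsets) {
  storage.mode(offsets) <- "integer"
  out <- .erode3d(as.vector(a), dim(a), offsets)
  array(out, dim(a))
}

#' Label connected components
#'
#' Two foreground voxels share a label iff they are connected under the
#' chosen voxel adjacency (6 = faces, 18 = faces+edges, 26 = full
#' neighborhood).  Labels are contiguous `1..K`, ordered by each
#' component's first voxel in the array's linear (raster) order, so the
#' labeling is deterministic.
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 6, 18 or 26 (default 26; thin diagonal neurites stay
#'   connected).
#' @return a [LabelVolume-class].
#' @export
connectedComponents <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  lab <- .cc_label3d(as.vector(mask@.Data), dim(mask@.Data), connectivity)
  LabelVolume(array(as.integer(lab), dim(mask@.Data)), mask@voxelSize,
              mask@origin)
}

#' Remove small components
#'
#' Keeps instances with `voxel_count >= minVoxels` (strictly smaller
#' components are removed, i.e. the boundary size survives) and relabels
#' survivors `1..K` preserving the original label order.
#'
#' @param l a [LabelVolume-class].
#' @param minVoxels positive integer size gate.
#' @return a [LabelVolume-class].
#' @export
sizeFilter <- function(l, minVoxels) {
  stopifnot(is(l, "LabelVolume"))
  minVoxels <- as.integer(minVoxels)
  if (is.na(minVoxels) || minVoxels < 1L)
    stop("minVoxels must be a positive integer", call. = FALSE)
  k <- nLabels(l)
  if (k == 0L) return(l)
  counts <- tabulate(l@.Data, nbins = k)
  keep <- counts >= minVoxels
  remap <- integer(k + 1L)                # index 1 = background
  remap[c(FALSE, keep)] <- seq_len(sum(keep))
  out <- l
  out@.Data <- array(remap[l@.Data + 1L], dim(l@.Data))
  out
}

#' Close one-voxel gaps
#'
#' Morphological closing with a 3x3x3 structuring element: foreground
#' voxels separated by a single background voxel become connected.  The
#' output is a superset of the input and the operation is idempotent.
#'
#' @param mask a [BinaryMask-class].
#' @return a [BinaryMask-class].
#' @export
closeUnitGaps <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  off <- .boxOffsets(1L)
  out <- mask
  out@.Data <- .erode(.dilate(mask@.Data, off), off)
  out
}

# classic 3D Bresenham between two 0-based voxel coordinates (z,y,x);
# returns a matrix of voxels including both endpoints
.bresenham3d <- function(p, q) {
  d <- q - p
  s <- sign(d)
  a <- abs(d)
  driving <- which.max(a)
  n <- a[driving]
  if (n == 0) return(matrix(p, 1L, 3L))
  pts <- matrix(0L, n + 1L, 3L)
  cur <- p
  err <- 2L * a - a[driving]   # per-axis error terms vs the driving axis
  pts[1L, ] <- cur
  for (i in seq_len(n)) {
    for (ax in 1:3) {
      if (ax == driving) next
      if (err[ax] > 0L) {
        cur[ax] <- cur[ax] + s[ax]
        err[ax] <- err[ax] - 2L * a[driving]
      }
      err[ax] <- err[ax] + 2L * a[ax]
    }
    cur[driving] <- cur[driving] + s[driving]
    pts[i + 1L, ] <- cur
  }
  pts
}

#' Bridge-spec constructor
#'
#' @param maxGap largest closable gap, in Euclidean voxel units (default 20).
#' @param iterations number of bridging rounds (default 4).
#' @param bridgeRadius dilation radius of the rasterized bridge (default 1).
#' @return a [BridgeSpec-class].
#' @export
bridgeSpec <- function(maxGap = 20, iterations = 4L, bridgeRadius = 1L) {
  new("BridgeSpec", maxGap = as.numeric(maxGap),
      iterations = as.integer(iterations),
      bridgeRadius = as.integer(bridgeRadius))
}

#' Bridge labeling gaps between components
#'
#' Iterative 3D component connecting: per round, components are labeled at
#' 26-connectivity; for every pair of components whose minimum Euclidean
#' voxel-center distance is at most `maxGap`, the straight line between the
#' closest voxel pair (arg-min; ties broken by the lowest raster-order
#' pair) is rasterized with 3D Bresenham and added to the foreground,
#' dilated by `bridgeRadius`.  Rounds repeat up to `iterations` times or
#' until a round adds no voxels.  The output is always a superset of the
#' input and the component count never increases within a round.
#'
#' Distances are measured in isotropic voxel units, matching how the gap
#' tolerance is stated; pass `spacing` to measure anisotropically instead.
#'
#' @param mask a [BinaryMask-class].
#' @param spec a [BridgeSpec-class].
#' @param spacing optional per-axis weights (z,y,x) for anisotropic gap
#'   measurement; default `c(1,1,1)`.
#' @return a [BinaryMask-class].
#' @export
bridgeComponents <- function(mask, spec = bridgeSpec(), spacing = c(1, 1, 1)) {
  stopifnot(is(mask, "BinaryMask"), is(spec, "BridgeSpec"))
  a <- mask@.Data
  d <- dim(a)
  off6 <- .boxOffsets(1L)
  off6 <- off6[rowSums(abs(off6)) == 1L, , drop = FALSE]
  ballOff <- .ballOffsets(spec@bridgeRadius)
  aniso <- !isTRUE(all(spacing == 1))
  for (iter in seq_len(spec@iterations)) {
    lab <- .cc_label3d(as.vector(a), d, 26L)
    k <- attr(lab, "n_labels")
    if (k < 2L) break
    lab <- array(as.integer(lab), d)
    # surface voxels only: interior voxels can never realize the minimum
    surf <- a & !.erode(a, off6)
    idx <- which(surf)                       # ascending = raster order
    coords <- arrayInd(idx, d) - 1L          # 0-based (z,y,x)
    labs <- lab[idx]
    bySurf <- split(seq_along(idx), labs)
    added <- FALSE
    bridge <- array(FALSE, d)
    ids <- as.integer(names(bySurf))
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (j <= i) next
        ci <- coords[bySurf[[i]], , drop = FALSE]
        cj <- coords[bySurf[[j]], , drop = FALSE]
        mp <- if (aniso)
          .minPairDistWeighted(ci, cj, spacing) else .min_pair_dist(ci, cj)
        if (sqrt(mp$dist2) <= spec@maxGap) {
          line <- .bresenham3d(ci[mp$i, ], cj[mp$j, ])
          bridge[line %*% c(1, d[1], d[1] * d[2]) + 1L] <- TRUE
          added <- TRUE
        }
      }
    }
    if (!added) break
    if (nrow(ballOff) > 0L) bridge <- .dilate(bridge, ballOff)
    a <- a | bridge
  }
  out <- mask
  out@.Data <- a
  out
}

# exhaustive weighted closest pair (anisotropic option); same tie-break
.minPairDistWeighted <- function(ci, cj, spacing) {
  best <- Inf; bi <- 1L; bj <- 1L
  wi <- sweep(ci, 2L, spacing, `*`)
  wj <- sweep(cj, 2L, spacing, `*`)
  for (i in seq_len(nrow(wi))) {
    dd <- (wj[, 1] - wi[i, 1])^2 + (wj[, 2] - wi[i, 2])^2 +
          (wj[, 3] - wi[i, 3])^2
    j <- which.min(dd)
    if (dd[j] < best) { best <- dd[j]; bi <- i; bj <- j }
  }
  list(dist2 = best, i = bi, j = bj)
}

#' Post-process a neuron channel into a binary neuron mask
#'
#' The full mask chain: global intensity threshold (Otsu/Li/manual), gap
#' bridging (defaults: gaps of 20 voxels or less, 4 iterations),
#' morphological closing of one-voxel gaps, connected-component analysis and
#' removal of components smaller than 2000 voxels.  A constant (e.g. empty)
#' volume yields an empty mask.
#'
#' @param v the neuron-channel [VoxelVolume-class].
#' @param cfg a [PipelineConfig-class]; its `maskThreshold`, `bridge`,
#'   `connectivity` and `maskMinSize` fields drive the chain.
#' @param keepIntermediates if `TRUE`, attach the per-stage intermediates as
#'   attribute `"intermediates"`.
#' @return the final [BinaryMask-class].
#' @export
postprocessNeuronMask <- function(v, cfg = pipelineConfig(),
                                  keepIntermediates = FALSE) {
  stopifnot(is(v, "VoxelVolume"), is(cfg, "PipelineConfig"))
  if (length(unique(as.vector(v@.Data))) < 2L) {
    return(BinaryMask(array(FALSE, dim(v@.Data)), v@voxelSize, v@origin))
  }
  t <- computeThreshold(v, cfg@maskThreshold)
  m1 <- applyThreshold(v, t)
  m2 <- bridgeComponents(m1, cfg@bridge,
                         spacing = if (cfg@anisotropicDistance)
                           v@voxelSize / min(v@voxelSize) else c(1, 1, 1))
  m3 <- closeUnitGaps(m2)
  lab <- connectedComponents(m3, cfg@connectivity)
  lab <- sizeFilter(lab, cfg@maskMinSize)
  out <- BinaryMask(lab@.Data > 0L, v@voxelSize, v@origin)
  if (keepIntermediates)
    attr(out, "intermediates") <- list(threshold = t, thresholded = m1,
                                       bridged = m2, closed = m3,
                                       components = lab)
  out
}
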