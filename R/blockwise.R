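#' Partition a volume into processing blocks
#'
#' Ceil-division tiling into cubic blocks (default edge 512) with a halo
#' (default 64): core boxes tile the volume exactly and pairwise disjointly
#' (edge blocks are smaller), each padded box is the core grown by `halo`
#' and clipped at the volume boundary.  Blocks are enumerated in the
#' array's linear order (z fastest), deterministically.
#'
#' @param shape integer(3) volume shape (z,y,x).
#' @param blockEdge positive block edge.
#' @param halo non-negative halo width.
#' @return a [BlockGrid-class]; `blocks` holds one row per block with
#'   0-based inclusive core and padded boxes.
#' @examples
#' nrow(blockGrid(c(1000, 1000, 1000), 512)@blocks)  # 8
#' @export
blockGrid <- function(shape, blockEdge = 512L, halo = 64L) {
  shape <- as.integer(shape)
  blockEdge <- as.integer(blockEdge)
  halo <- as.integer(halo)
  if (any(shape < 1L)) stop("shape must be positive", call. = FALSE)
  if (is.na(blockEdge) || blockEdge < 1L)
    stop("blockEdge must be a positive integer", call. = FALSE)
  if (is.na(halo) || halo < 0L)
    stop("halo must be a non-negative integer", call. = FALSE)
  starts <- lapply(shape, function(n) seq.int(0L, n - 1L, by = blockEdge))
  g <- expand.grid(z = starts[[1]], y = starts[[2]], x = starts[[3]],
                   KEEP.OUT.ATTRS = FALSE)   # z varies fastest
  core <- cbind(
    zmin = g$z, zmax = pmin(g$z + blockEdge, shape[1]) - 1L,
    ymin = g$y, ymax = pmin(g$y + blockEdge, shape[2]) - 1L,
    xmin = g$x, xmax = pmin(g$x + blockEdge, shape[3]) - 1L)
  pad <- cbind(
    zmin = pmax(core[, "zmin"] - halo, 0L),
    zmax = pmin(core[, "zmax"] + halo, shape[1] - 1L),
    ymin = pmax(core[, "ymin"] - halo, 0L),
    ymax = pmin(core[, "ymax"] + halo, shape[2] - 1L),
    xmin = pmax(core[, "xmin"] - halo, 0L),
    xmax = pmin(core[, "xmax"] + halo, shape[3] - 1L))
  blocks <- data.frame(block = seq_len(nrow(core)))
  for (nm in colnames(core)) blocks[[paste0("core_", nm)]] <- core[, nm]
  for (nm in colnames(pad)) blocks[[paste0("pad_", nm)]] <- pad[, nm]
  new("BlockGrid", volumeShape = shape, blockEdge = blockEdge, halo = halo,
      blocks = blocks)
}

setMethod("show", "BlockGrid", function(object) {
  cat("BlockGrid:", nrow(object@blocks), "blocks of edge",
      object@blockEdge, "with halo", object@halo, "over volume",
      paste(object@volumeShape, collapse = " x "), "\n")
})

.coreBox <- function(grid, i) {
  b <- grid@blocks[i, ]
  c(b$core_zmin, b$core_zmax, b$core_ymin, b$core_ymax, b$core_xmin,
    b$core_xmax)
}

.padBox <- function(grid, i) {
  b <- grid@blocks[i, ]
  c(b$pad_zmin, b$pad_zmax, b$pad_ymin, b$pad_ymax, b$pad_xmin, b$pad_xmax)
}

#' Blocks whose core contains neuron mask
#'
#' Identifies the blocks worth processing: exactly those whose core box
#' contains at least one mask voxel (subvolumes without a neuron mask are
#' ignored).  Skipping the other blocks changes only the work done, never
#' a result, because a site with no mask anywhere near it can never pass
#' the assignment rule.
#'
#' @param grid a [BlockGrid-class].
#' @param mask a [BinaryMask-class] with the grid's shape.
#' @return integer vector of block indices.
#' @export
nonemptyBlocks <- function(grid, mask) {
  stopifnot(is(grid, "BlockGrid"), is(mask, "BinaryMask"))
  if (!identical(dim(mask@.Data), as.integer(grid@volumeShape)))
    stop("nonemptyBlocks: mask shape does not match grid", call. = FALSE)
  keep <- vapply(seq_len(nrow(grid@blocks)), function(i) {
    any(.sliceBox(mask@.Data, .coreBox(grid, i)))
  }, logical(1))
  which(keep)
}

# ---- blockwise connected components ----------------------------------------

.unionFind <- function(n) {
  env <- new.env(parent = emptyenv())
  env$parent <- seq_len(n)
  env$find <- function(i) {
    p <- env$parent
    while (p[i] != i) i <- p[i]
    i
  }
  env$union <- function(i, j) {
    ri <- env$find(i)
    rj <- env$find(j)
    if (ri != rj) env$parent[max(ri, rj)] <- min(ri, rj)
  }
  env
}

# half-space neighbor offsets (one per unordered adjacency direction)
.halfOffsets <- function(connectivity) {
  off <- .boxOffsets(1L)
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1L, , drop = FALSE]
  if (connectivity == 18L) off <- off[rowSums(abs(off)) <= 2L, , drop = FALSE]
  keep <- off[, 1] > 0L | (off[, 1] == 0L & off[, 2] > 0L) |
    (off[, 1] == 0L & off[, 2] == 0L & off[, 3] > 0L)
  off[keep, , drop = FALSE]
}

#' Connected components computed blockwise
#'
#' Labels each block's core independently, then unifies instances across
#' block boundaries with a union-find over all adjacent foreground voxel
#' pairs, and relabels `1..K` by raster order of first voxel.  The result
#' is identical to [connectedComponents()] on the whole volume for any
#' input, and is independent of block processing order.
#'
#' @param mask a [BinaryMask-class].
#' @param grid a [BlockGrid-class] matching the mask shape.
#' @param connectivity 6, 18 or 26.
#' @return a [LabelVolume-class].
#' @export
blockwiseComponents <- function(mask, grid, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"), is(grid, "BlockGrid"))
  d <- dim(mask@.Data)
  if (!identical(d, as.integer(grid@volumeShape)))
    stop("blockwiseComponents: mask shape does not match grid", call. = FALSE)
  lab <- array(0L, d)
  offset <- 0L
  for (i in seq_len(nrow(grid@blocks))) {
    box <- .coreBox(grid, i)
    sub <- .sliceBox(mask@.Data, box)
    sl <- .cc_label3d(as.vector(sub), dim(sub), as.integer(connectivity))
    k <- attr(sl, "n_labels")
    if (k == 0L) next
    sl <- array(as.integer(sl), dim(sub))
    sl[sl > 0L] <- sl[sl > 0L] + offset
    lab[(box[1] + 1L):(box[2] + 1L), (box[3] + 1L):(box[4] + 1L),
        (box[5] + 1L):(box[6] + 1L)] <- sl
    offset <- offset + k
  }
  if (offset == 0L)
    return(LabelVolume(lab, mask@voxelSize, mask@origin))
  # merge across boundaries: every adjacent foreground pair with differing
  # labels is unified (cross-core pairs are the only such pairs)
  uf <- .unionFind(offset)
  for (r in seq_len(nrow(.halfOffsets(as.integer(connectivity))))) {
    o <- .halfOffsets(as.integer(connectivity))[r, ]
    az <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
    ay <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
    ax <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
    A <- lab[az, ay, ax, drop = FALSE]
    B <- lab[az + o[1], ay + o[2], ax + o[3], drop = FALSE]
    sel <- A > 0L & B > 0L & A != B
    if (any(sel)) {
      pairs <- unique(cbind(A[sel], B[sel]))
      for (p in seq_len(nrow(pairs))) uf$union(pairs[p, 1], pairs[p, 2])
    }
  }
  roots <- vapply(seq_len(offset), uf$find, integer(1))
  remap <- c(0L, roots)
  lab <- array(remap[lab + 1L], d)
  .relabelRaster(LabelVolume(lab, mask@voxelSize, mask@origin))
}

# ---- blockwise site detection and connectivity ------------------------------

# concrete per-volume provider: freeze scaled_intensity percentiles on the
# whole volume so per-block application equals the global computation
.resolveProvider <- function(v, provider) {
  if (provider$name == "scaled_intensity" &&
      (is.null(provider$params$lo) || is.null(provider$params$hi))) {
    vals <- as.numeric(v@.Data)
    qs <- stats::quantile(vals, c(0.01, 0.999), names = FALSE)
    if (qs[2] <= qs[1]) qs <- range(vals)  # same fallback as the provider
    lo <- if (is.null(provider$params$lo)) qs[1] else provider$params$lo
    hi <- if (is.null(provider$params$hi)) qs[2] else provider$params$hi
    return(probabilityProvider("scaled_intensity", lo = lo, hi = hi))
  }
  provider
}

#' Detect sites blockwise
#'
#' Runs [detectSites()] on each padded block; an instance is owned by the
#' block whose core contains the voxel holding its centroid (the
#' deduplication rule), and owned instances are merged into one label
#' volume, relabeled in raster order.  Results equal the unblocked
#' [detectSites()] whenever every site fits within the halo; a site whose
#' bounding box presses against a padded block face (away from the volume
#' boundary) triggers an overflow warning naming the site, as it may have
#' been split.
#'
#' @inheritParams detectSites
#' @param grid a [BlockGrid-class].
#' @return same structure as [detectSites()].
#' @export
blockwiseDetectSites <- function(v, provider, profile, grid) {
  stopifnot(is(v, "VoxelVolume"), is(grid, "BlockGrid"))
  d <- dim(v@.Data)
  if (!identical(d, as.integer(grid@volumeShape)))
    stop("blockwiseDetectSites: volume shape does not match grid",
         call. = FALSE)
  minDiam <- 2 * profile@minSizeVoxels^(1 / 3) * 4
  if (grid@halo > 0L && grid@halo < minDiam && nrow(grid@blocks) > 1L)
    warning(sprintf(
      "halo %d may be smaller than the expected site diameter (~%.0f); sites spanning block faces may be split",
      grid@halo, minDiam), call. = FALSE)
  provider <- .resolveProvider(v, provider)
  lab <- array(0L, d)
  nextId <- 0L
  for (i in seq_len(nrow(grid@blocks))) {
    pad <- .padBox(grid, i)
    core <- .coreBox(grid, i)
    sub <- cropRoi(v, pad)
    det <- detectSites(sub, provider, profile)
    if (nrow(det$sites) == 0L) next
    sl <- det$labels@.Data
    st <- det$sites
    # global centroid voxel decides ownership
    cz <- floor(st$centroid_z) + pad[1]
    cy <- floor(st$centroid_y) + pad[3]
    cx <- floor(st$centroid_x) + pad[5]
    owned <- cz >= core[1] & cz <= core[2] & cy >= core[3] & cy <= core[4] &
      cx >= core[5] & cx <= core[6]
    # overflow check: bbox touching a padded face that is not a volume face
    pd <- dim(sl)
    for (s in which(owned)) {
      touch <-
        (st$bbox_zmin[s] == 0L && pad[1] > 0L) ||
        (st$bbox_zmax[s] == pd[1] - 1L && pad[2] < d[1] - 1L) ||
        (st$bbox_ymin[s] == 0L && pad[3] > 0L) ||
        (st$bbox_ymax[s] == pd[2] - 1L && pad[4] < d[2] - 1L) ||
        (st$bbox_xmin[s] == 0L && pad[5] > 0L) ||
        (st$bbox_xmax[s] == pd[3] - 1L && pad[6] < d[3] - 1L)
      if (touch)
        warning(sprintf(
          "site %d in block %d reaches the padded block boundary; result may be split",
          st$id[s], i), call. = FALSE)
    }
    if (!any(owned)) next
    ids <- st$id[owned]
    sel <- which(sl %in% ids)
    co <- arrayInd(sel, pd)
    gidx <- (co[, 1] + pad[1]) + d[1] * ((co[, 2] - 1L + pad[3]) +
              d[2] * (co[, 3] - 1L + pad[5]))
    remap <- integer(max(st$id) + 1L)
    remap[ids + 1L] <- nextId + seq_along(ids)
    lab[gidx] <- remap[sl[sel] + 1L]
    nextId <- nextId + length(ids)
  }
  out <- .relabelRaster(LabelVolume(lab, v@voxelSize, v@origin))
  list(labels = out, sites = .siteTable(out))
}

#' Run a workflow with blockwise detection
#'
#' Identical contract to [runWorkflow()], with site detection executed per
#' block via [blockwiseDetectSites()]; assignment and contacts are computed
#' after the cross-block merge, so the report equals the unblocked pipeline
#' whenever all sites fit within the halo.  A grid with a single block is
#' exactly the unblocked pipeline.
#'
#' @inheritParams runWorkflow
#' @param grid a [BlockGrid-class]; default derives from `cfg`'s
#'   `blockEdge`/`halo` and the input shape.
#' @return a [WorkflowReport-class].
#' @export
blockwiseDetectAndConnect <- function(channels, cfg = pipelineConfig(),
                                      grid = NULL, kind = 2L,
                                      provider = probabilityProvider("scaled_intensity"),
                                      markerRole = "presynaptic") {
  ref <- channels[[1]]
  if (is.null(grid))
    grid <- blockGrid(dim(ref@.Data), cfg@blockEdge, cfg@halo)
  blockedDetect <- function(v, prof)
    blockwiseDetectSites(v, provider, prof, grid)
  .runWorkflowImpl(as.integer(kind), channels, cfg, provider, markerRole,
                   detector = blockedDetect)
}
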