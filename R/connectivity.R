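#' Pipeline-config constructor
#'
#' All arguments default to the published operating point; see
#' [PipelineConfig-class].
#'
#' @param assignmentFraction minimum fraction of a site's volume inside the
#'   neuron mask for assignment (inclusive; default 0.5).
#' @param contactFraction minimum overlap fraction of the query object for a
#'   contact (inclusive; default 0.001).
#' @param contactDilation voxels by which the query site is dilated before
#'   measuring contact (default 0: genuine voxel overlap).
#' @param presynProfile,postsynProfile,gapJunctionProfile per-role
#'   [SegmentationProfile-class] objects.
#' @param maskThreshold a [ThresholdSpec-class] for neuron-mask
#'   post-processing.
#' @param bridge a [BridgeSpec-class].
#' @param maskMinSize neuron-component size gate (default 2000).
#' @param blockEdge processing-block edge (default 512).
#' @param halo block halo in voxels (default 64).
#' @param connectivity voxel adjacency, 6/18/26 (default 26).
#' @param anisotropicDistance measure gaps/distances in nm-weighted voxel
#'   units instead of isotropic voxels (default FALSE).
#' @param seed RNG seed (phantom generation only).
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(assignmentFraction = 0.5,
                           contactFraction = 0.001,
                           contactDilation = 0L,
                           presynProfile = segmentationProfile("presynaptic"),
                           postsynProfile = segmentationProfile("postsynaptic"),
                           gapJunctionProfile = segmentationProfile("gap_junction"),
                           maskThreshold = thresholdSpec("otsu"),
                           bridge = bridgeSpec(),
                           maskMinSize = 2000L,
                           blockEdge = 512L,
                           halo = 64L,
                           connectivity = 26L,
                           anisotropicDistance = FALSE,
                           seed = NA_integer_) {
  new("PipelineConfig",
      assignmentFraction = as.numeric(assignmentFraction),
      contactFraction = as.numeric(contactFraction),
      contactDilation = as.integer(contactDilation),
      presynProfile = presynProfile,
      postsynProfile = postsynProfile,
      gapJunctionProfile = gapJunctionProfile,
      maskThreshold = maskThreshold,
      bridge = bridge,
      maskMinSize = as.integer(maskMinSize),
      blockEdge = as.integer(blockEdge),
      halo = as.integer(halo),
      connectivity = as.integer(connectivity),
      anisotropicDistance = anisotropicDistance,
      seed = as.integer(seed))
}

#' Assign synaptic sites to a neuron mask
#'
#' A site is assigned iff the fraction of its voxels inside the mask is at
#' least `fraction` (inclusive, matching the "50% or more" rule).  Every
#' site's fraction is reported regardless of outcome.
#'
#' @param sites a [LabelVolume-class] of site instances.
#' @param mask a [BinaryMask-class] of the neuron, same shape.
#' @param fraction inclusive assignment threshold (default 0.5).
#' @return data frame with `id`, `voxel_count`, `overlap_voxels`,
#'   `overlap_fraction`, `assigned`.
#' @export
assignSitesToMask <- function(sites, mask, fraction = 0.5) {
  stopifnot(is(sites, "LabelVolume"), is(mask, "BinaryMask"))
  if (!identical(dim(sites@.Data), dim(mask@.Data)))
    stop("assignSitesToMask: shapes differ", call. = FALSE)
  k <- nLabels(sites)
  if (k == 0L)
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      overlap_voxels = integer(0),
                      overlap_fraction = numeric(0), assigned = logical(0)))
  total <- tabulate(sites@.Data, nbins = k)
  inside <- tabulate(sites@.Data[mask@.Data], nbins = k)
  frac <- inside / total
  data.frame(id = seq_len(k), voxel_count = total, overlap_voxels = inside,
             overlap_fraction = frac, assigned = frac >= fraction)
}

# overlap table between two label volumes: one row per (a, b) label pair
# with overlap voxel count and the 0-based centroid of the overlap set
.overlapPairs <- function(a, b) {
  d <- dim(a)
  idx <- which(a > 0L & b > 0L)
  if (length(idx) == 0L)
    return(data.frame(a = integer(0), b = integer(0),
                      overlap = integer(0), cz = numeric(0), cy = numeric(0),
                      cx = numeric(0)))
  co <- arrayInd(idx, d) - 1L
  key <- paste(a[idx], b[idx], sep = "_")
  agg <- rowsum(cbind(n = 1, z = co[, 1], y = co[, 2], x = co[, 3]), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
  out <- data.frame(a = as.integer(parts[, 1]), b = as.integer(parts[, 2]),
                    overlap = as.integer(agg[, "n"]),
                    cz = agg[, "z"] / agg[, "n"],
                    cy = agg[, "y"] / agg[, "n"],
                    cx = agg[, "x"] / agg[, "n"])
  out[order(out$a, out$b), , drop = FALSE]
}

# dilate each query instance independently by r voxels (ball) within its
# padded bounding box; returns a list of per-id voxel index vectors
.dilatedInstanceVoxels <- function(lab, r) {
  d <- dim(lab)
  k <- max(lab, 0L)
  st <- .label_stats3d(as.vector(lab), d, k)
  off <- .ballOffsets(r)
  res <- vector("list", k)
  for (i in seq_len(k)) {
    if (st$count[i] == 0) next
    lo <- pmax(c(st$zmin[i], st$ymin[i], st$xmin[i]) - r, 0L)
    hi <- pmin(c(st$zmax[i], st$ymax[i], st$xmax[i]) + r, d - 1L)
    box <- c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])
    sub <- .sliceBox(lab, box) == i
    sub <- .dilate(sub, off)
    subIdx <- which(sub)
    co <- arrayInd(subIdx, dim(sub)) - 1L
    co <- sweep(co, 2L, lo, `+`)
    res[[i]] <- co %*% c(1, d[1], d[1] * d[2]) + 1L
  }
  res
}

.emptyConnections <- function() {
  data.frame(pre_site_id = integer(0), post_object_id = integer(0),
             post_object_type = character(0), overlap_voxels = integer(0),
             overlap_fraction = numeric(0), contact_centroid_z = numeric(0),
             contact_centroid_y = numeric(0), contact_centroid_x = numeric(0))
}

#' Find contacts between postsynaptic and presynaptic sites
#'
#' For each postsynaptic site q (the query), the overlap with every
#' presynaptic site p is measured (optionally after dilating q by
#' `contactDilation` voxels); a connection is emitted iff
#' `overlap_voxels / |undilated q| >= contactFraction` (inclusive — at the
#' default 0.001 essentially any contact counts).  A query site may contact
#' several presynaptic sites (polyadic synapses); each pair emits at most
#' one connection.  The contact centroid is the centroid of the overlap
#' voxel set.
#'
#' @param pre a [LabelVolume-class] of presynaptic sites (typically already
#'   restricted to the sites assigned to neuron 1).
#' @param post a [LabelVolume-class] of postsynaptic sites, same shape.
#' @param cfg a [PipelineConfig-class] (uses `contactFraction`,
#'   `contactDilation`).
#' @return connection data frame (`pre_site_id`, `post_object_id`,
#'   `post_object_type = "site"`, `overlap_voxels`, `overlap_fraction`,
#'   contact centroid columns).
#' @export
findSiteSiteContacts <- function(pre, post, cfg = pipelineConfig()) {
  stopifnot(is(pre, "LabelVolume"), is(post, "LabelVolume"))
  if (!identical(dim(pre@.Data), dim(post@.Data)))
    stop("findSiteSiteContacts: shapes differ", call. = FALSE)
  kq <- nLabels(post)
  if (kq == 0L || nLabels(pre) == 0L) return(.emptyConnections())
  qSize <- tabulate(post@.Data, nbins = kq)
  if (cfg@contactDilation == 0L) {
    ov <- .overlapPairs(post@.Data, pre@.Data)
  } else {
    vox <- .dilatedInstanceVoxels(post@.Data, cfg@contactDilation)
    d <- dim(post@.Data)
    q <- array(0L, d)
    rows <- list()
    for (i in seq_along(vox)) {
      if (is.null(vox[[i]])) next
      pv <- pre@.Data[vox[[i]]]
      sel <- pv > 0L
      if (!any(sel)) next
      co <- arrayInd(vox[[i]][sel], d) - 1L
      sub <- rowsum(cbind(n = 1, z = co[, 1], y = co[, 2], x = co[, 3]),
                    pv[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        a = i, b = as.integer(rownames(sub)), overlap = as.integer(sub[, "n"]),
        cz = sub[, "z"] / sub[, "n"], cy = sub[, "y"] / sub[, "n"],
        cx = sub[, "x"] / sub[, "n"])
    }
    ov <- if (length(rows)) do.call(rbind, rows) else
      data.frame(a = integer(0), b = integer(0), overlap = integer(0),
                 cz = numeric(0), cy = numeric(0), cx = numeric(0))
    ov <- ov[order(ov$a, ov$b), , drop = FALSE]
  }
  frac <- ov$overlap / qSize[ov$a]
  keep <- frac >= cfg@contactFraction
  data.frame(pre_site_id = ov$b[keep], post_object_id = ov$a[keep],
             post_object_type = rep("site", sum(keep)),
             overlap_voxels = ov$overlap[keep], overlap_fraction = frac[keep],
             contact_centroid_z = ov$cz[keep],
             contact_centroid_y = ov$cy[keep],
             contact_centroid_x = ov$cx[keep],
             row.names = NULL)
}

#' Find contacts between presynaptic sites and a neuron mask
#'
#' Query is each presynaptic site; same inclusive contact rule with the
#' target neuron's full binary mask (the mask covers whole neurites, not a
#' hollow shell).
#'
#' @param pre a [LabelVolume-class] of presynaptic sites.
#' @param mask the target neuron's [BinaryMask-class], same shape.
#' @param cfg a [PipelineConfig-class].
#' @return connection data frame with `post_object_type = "mask"` and
#'   `post_object_id = 1`.
#' @export
findSiteMaskContacts <- function(pre, mask, cfg = pipelineConfig()) {
  stopifnot(is(pre, "LabelVolume"), is(mask, "BinaryMask"))
  if (!identical(dim(pre@.Data), dim(mask@.Data)))
    stop("findSiteMaskContacts: shapes differ", call. = FALSE)
  kq <- nLabels(pre)
  if (kq == 0L) return(.emptyConnections())
  qSize <- tabulate(pre@.Data, nbins = kq)
  maskLab <- array(as.integer(mask@.Data), dim(mask@.Data))
  if (cfg@contactDilation == 0L) {
    ov <- .overlapPairs(pre@.Data, maskLab)
  } else {
    vox <- .dilatedInstanceVoxels(pre@.Data, cfg@contactDilation)
    d <- dim(pre@.Data)
    rows <- list()
    for (i in seq_along(vox)) {
      if (is.null(vox[[i]])) next
      sel <- mask@.Data[vox[[i]]]
      if (!any(sel)) next
      co <- arrayInd(vox[[i]][sel], d) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        a = i, b = 1L, overlap = sum(sel), cz = mean(co[, 1]),
        cy = mean(co[, 2]), cx = mean(co[, 3]))
    }
    ov <- if (length(rows)) do.call(rbind, rows) else
      data.frame(a = integer(0), b = integer(0), overlap = integer(0),
                 cz = numeric(0), cy = numeric(0), cx = numeric(0))
  }
  frac <- ov$overlap / qSize[ov$a]
  keep <- frac >= cfg@contactFraction
  data.frame(pre_site_id = ov$a[keep], post_object_id = ov$b[keep],
             post_object_type = rep("mask", sum(keep)),
             overlap_voxels = ov$overlap[keep], overlap_fraction = frac[keep],
             contact_centroid_z = ov$cz[keep],
             contact_centroid_y = ov$cy[keep],
             contact_centroid_x = ov$cx[keep],
             row.names = NULL)
}
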