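#' Segmentation-profile constructor
#'
#' Role defaults follow the published operating point: probability
#' threshold 0.8 for every role; minimum instance size 400 voxels for
#' presynaptic markers (unclustered antibody signal is smaller than 400
#' voxels) and 200 for postsynaptic and gap-junction markers.
#'
#' @param role `"presynaptic"`, `"postsynaptic"` or `"gap_junction"`.
#' @param probThreshold probability threshold in (0,1); default 0.8.
#' @param minSizeVoxels inclusive-keep size gate; default 400 (presynaptic)
#'   or 200 (postsynaptic, gap_junction).
#' @param minSeedSeparation minimum Euclidean distance (voxels) between
#'   watershed seeds; default 3.
#' @return a [SegmentationProfile-class].
#' @export
segmentationProfile <- function(role = c("presynaptic", "postsynaptic",
                                         "gap_junction"),
                                probThreshold = 0.8,
                                minSizeVoxels = NULL,
                                minSeedSeparation = 3L) {
  role <- match.arg(role)
  if (is.null(minSizeVoxels))
    minSizeVoxels <- if (role == "presynaptic") 400L else 200L
  new("SegmentationProfile", role = role,
      probThreshold = as.numeric(probThreshold),
      minSizeVoxels = as.integer(minSizeVoxels),
      minSeedSeparation = as.integer(minSeedSeparation))
}

# ---- probability providers --------------------------------------------------
# Registry of voxel-classifier backends.  The built-in "scaled_intensity"
# provider rescales raw intensity to [0,1]; "external_model" wraps any
# user-supplied callable (e.g. a neural-network inference function) that
# maps a volume array to a same-shape probability array.  No trained
# weights ship with the package.

.providerRegistry <- new.env(parent = emptyenv())

#' Register a probability provider
#'
#' @param name provider name.
#' @param fun function `(array, params) -> array` returning values in
#'   \eqn{[0,1]} with the input's shape.
#' @return invisibly `NULL`.
#' @export
registerProbabilityProvider <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .providerRegistry)
  invisible(NULL)
}

#' List registered probability providers
#' @return character vector of provider names.
#' @export
listProbabilityProviders <- function() {
  sort(ls(.providerRegistry))
}

#' Probability-provider handle
#'
#' @param name registered provider name (`"scaled_intensity"` or
#'   `"external_model"` are built in).
#' @param ... provider parameters.  `scaled_intensity` accepts `lo`/`hi`
#'   (else the 1st/99.9th intensity percentiles are used);
#'   `external_model` requires `fun`, the classifier callable.
#' @return a provider object usable with [probabilityMap()].
#' @export
probabilityProvider <- function(name, ...) {
  structure(list(name = name, params = list(...)),
            class = "ProbabilityProvider")
}

.scaledIntensity <- function(a, params) {
  vals <- as.numeric(a)
  lo <- params$lo
  hi <- params$hi
  if (is.null(lo) || is.null(hi)) {
    qs <- stats::quantile(vals, c(0.01, 0.999), names = FALSE)
    if (qs[2] <= qs[1]) qs <- range(vals)  # sparse signal: percentile window
    if (is.null(lo)) lo <- qs[1]           # collapses, rescale the full range
    if (is.null(hi)) hi <- qs[2]
  }
  if (hi <= lo) return(array(0, dim(a)))   # degenerate (constant) input
  array(pmin(pmax((vals - lo) / (hi - lo), 0), 1), dim(a))
}

.externalModel <- function(a, params) {
  if (is.null(params$fun) || !is.function(params$fun))
    stop("external_model provider requires a 'fun' parameter (the ",
         "voxel-classifier callable)", call. = FALSE)
  out <- params$fun(a)
  if (!identical(dim(out), dim(a)))
    stop("external model must preserve the input shape", call. = FALSE)
  out
}

#' Compute a probability map
#'
#' Applies the provider to the raw volume, yielding a same-shape volume of
#' voxel probabilities in \eqn{[0,1]} (the role played by the trained 3D
#' U-Net in the original pipeline; any voxel classifier slots in here).
#'
#' @param v a [VoxelVolume-class].
#' @param provider a [probabilityProvider()] handle.
#' @return a [VoxelVolume-class] of probabilities.
#' @export
probabilityMap <- function(v, provider = probabilityProvider("scaled_intensity")) {
  stopifnot(is(v, "VoxelVolume"))
  if (!exists(provider$name, envir = .providerRegistry))
    stop("unknown probability provider '", provider$name,
         "'; registered providers: ",
         paste(listProbabilityProviders(), collapse = ", "), call. = FALSE)
  fun <- get(provider$name, envir = .providerRegistry)
  p <- fun(v@.Data, provider$params)
  if (min(p) < 0 || max(p) > 1)
    stop("provider returned probabilities outside [0,1]", call. = FALSE)
  VoxelVolume(p, v@voxelSize, v@origin)
}

# ---- watershed instance segmentation ---------------------------------------

# deterministic seed selection: regional maxima of the distance transform
# quantized to whole voxels (sub-voxel ridge bumps from rasterization merge
# into one plateau, the h-maxima idea at h = 1 voxel), each plateau
# collapsed to its first raster voxel, then greedy suppression (within each
# connected component) so no two accepted seeds lie closer than
# minSeedSeparation; candidates are visited by decreasing distance value,
# ties by raster order.
.watershedSeeds <- function(edt, maskArr, comp, minSep) {
  d <- dim(maskArr)
  q <- floor(sqrt(edt) + 1e-9)
  mx <- .regional_maxima3d(as.vector(q), as.vector(maskArr), d)
  mx <- array(mx, d)
  plat <- .cc_label3d(as.vector(mx), d, 26L)
  np <- attr(plat, "n_labels")
  if (np == 0L) return(list(seeds = array(0L, d), n = 0L))
  plat <- array(as.integer(plat), d)
  platVec <- as.vector(plat)
  first <- match(seq_len(np), platVec)           # first raster voxel per plateau
  sq <- sqrt(as.vector(edt))
  inPlat <- which(platVec > 0L)
  candMax <- vapply(split(sq[inPlat], platVec[inPlat]), max, numeric(1))
  candMax <- candMax[order(as.integer(names(candMax)))]
  ord <- order(-candMax, first)
  # exact prominence test at h = 1 voxel: candidates separated from a
  # higher (or equal, already accepted) peak only by a dip shallower than
  # one voxel are rasterization artifacts, not separate objects
  keepH <- .hmax_accept(sq, as.vector(maskArr), d, platVec,
                        as.integer(first), as.numeric(candMax),
                        as.integer(ord), 1.0)
  surviving <- which(keepH)
  np <- length(surviving)
  if (np == 0L) return(list(seeds = array(0L, d), n = 0L))
  first <- first[surviving]
  vals <- candMax[surviving]
  ord <- order(-vals, first)
  coords <- arrayInd(first, d) - 1L
  compId <- comp[first]
  accepted <- integer(0)
  sep2 <- as.numeric(minSep)^2
  for (c_i in ord) {
    ok <- TRUE
    for (a_i in accepted) {
      if (compId[a_i] != compId[c_i]) next
      dd <- sum((coords[a_i, ] - coords[c_i, ])^2)
      if (dd < sep2) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, c_i)
  }
  accepted <- accepted[order(first[accepted])]   # relabel in raster order
  seeds <- array(0L, d)
  seeds[first[accepted]] <- seq_along(accepted)
  list(seeds = seeds, n = length(accepted))
}

#' Split a binary mask into instances by distance-transform watershed
#'
#' Seeds are the local maxima of the Euclidean distance transform of the
#' mask (plateaus contribute one seed at their first raster voxel),
#' suppressed so that no two seeds within the same connected component lie
#' closer than `minSeedSeparation` (candidates processed by decreasing
#' distance value, ties by raster order — no randomness anywhere).  The
#' negated distance transform is then flooded from the seeds, restricted to
#' the foreground.  The output labels partition the foreground exactly; a
#' component with a single surviving seed keeps a single label.
#'
#' @param mask a [BinaryMask-class].
#' @param minSeedSeparation minimum seed distance in voxels (default 3).
#' @param spacing per-axis distance weights (z,y,x); default isotropic.
#' @return a [LabelVolume-class].
#' @export
watershedInstances <- function(mask, minSeedSeparation = 3L,
                               spacing = c(1, 1, 1)) {
  stopifnot(is(mask, "BinaryMask"))
  a <- mask@.Data
  d <- dim(a)
  if (!any(a))
    return(LabelVolume(array(0L, d), mask@voxelSize, mask@origin))
  edt <- array(.edt3d_sq(as.vector(a), d, as.numeric(spacing)), d)
  comp <- array(as.integer(.cc_label3d(as.vector(a), d, 26L)), d)
  s <- .watershedSeeds(edt, a, comp, minSeedSeparation)
  lab <- .watershed3d(as.vector(edt), as.vector(s$seeds), as.vector(a), d, 26L)
  LabelVolume(array(as.integer(lab), d), mask@voxelSize, mask@origin)
}

# ---- site extraction --------------------------------------------------------

# per-instance records: id, voxel_count, centroid (0-based z,y,x mean voxel
# coordinate), inclusive bbox, per-axis extents
.siteTable <- function(l) {
  k <- nLabels(l)
  if (k == 0L) {
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), bbox_zmin = integer(0),
                      bbox_zmax = integer(0), bbox_ymin = integer(0),
                      bbox_ymax = integer(0), bbox_xmin = integer(0),
                      bbox_xmax = integer(0), extent_z = integer(0),
                      extent_y = integer(0), extent_x = integer(0)))
  }
  st <- .label_stats3d(as.vector(l@.Data), dim(l@.Data), k)
  data.frame(id = seq_len(k),
             voxel_count = as.integer(st$count),
             centroid_z = st$sum_z / st$count,
             centroid_y = st$sum_y / st$count,
             centroid_x = st$sum_x / st$count,
             bbox_zmin = st$zmin, bbox_zmax = st$zmax,
             bbox_ymin = st$ymin, bbox_ymax = st$ymax,
             bbox_xmin = st$xmin, bbox_xmax = st$xmax,
             extent_z = st$zmax - st$zmin + 1L,
             extent_y = st$ymax - st$ymin + 1L,
             extent_x = st$xmax - st$xmin + 1L)
}

#' Detect synaptic-site instances
#'
#' The post-classifier site pipeline: probability map, probability
#' threshold (foreground = probability >= threshold, default 0.8),
#' distance-transform watershed into instances, and the role-specific
#' inclusive size gate (default 400 voxels presynaptic, 200 postsynaptic /
#' gap junction).
#'
#' @param v the marker-channel [VoxelVolume-class].
#' @param provider a [probabilityProvider()].
#' @param profile a [SegmentationProfile-class].
#' @return a list with `labels` (a [LabelVolume-class], labels `1..K` in
#'   raster order of first voxel) and `sites` (per-instance data frame
#'   with voxel counts, 0-based centroids and inclusive bounding boxes).
#' @export
detectSites <- function(v, provider = probabilityProvider("scaled_intensity"),
                        profile = segmentationProfile("presynaptic")) {
  stopifnot(is(v, "VoxelVolume"), is(profile, "SegmentationProfile"))
  p <- probabilityMap(v, provider)
  m <- applyThreshold(p, profile@probThreshold)
  lab <- watershedInstances(m, profile@minSeedSeparation)
  lab <- sizeFilter(lab, profile@minSizeVoxels)
  lab <- .relabelRaster(lab)
  list(labels = lab, sites = .siteTable(lab))
}

# relabel 1..K by raster order of each label's first voxel (sizeFilter
# preserves order already; this normalizes labels from merged sources too)
.relabelRaster <- function(l) {
  k <- nLabels(l)
  if (k == 0L) return(l)
  first <- match(seq_len(k), as.vector(l@.Data))
  present <- which(!is.na(first))
  remap <- integer(k + 1L)
  remap[present + 1L] <- rank(first[present], ties.method = "first")
  out <- l
  out@.Data <- array(remap[l@.Data + 1L], dim(l@.Data))
  out
}
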