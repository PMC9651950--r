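#' Phantom-spec constructor
#'
#' Parameters of the synthetic ground-truth generator.  The defaults
#' emulate the statistical structure the pipeline assumes: tubular neurons
#' (bounded-curvature random-walk tubes) with short labeling gaps that the
#' default 20-voxel bridging closes, presynaptic ellipsoids of 450-3000
#' voxels seated on bouton-like swellings of their neuron, apposed
#' postsynaptic sites sharing a small voxel overlap with their partner,
#' and sub-gate nonspecific puncta (20-350 voxels, below the presynaptic
#' 400-voxel gate) in the presynaptic channel.
#'
#' @param volumeShape volume shape (z,y,x); default 256^3.
#' @param nNeurons number of neurons; default 3.
#' @param tubeRadius neurite tube radius in voxels; default 4.
#' @param tubeSteps,stepLength random-walk control points and step length;
#'   defaults 220 and 6 (about 1300 voxels of arclength per neuron).
#' @param gapCount,gapLength labeling gaps per neuron and their length in
#'   voxels (default 2 gaps of 10; kept at 15 or less so bridging at 20
#'   closes them).
#' @param nPresynPerNeuron presynaptic sites per neuron; default 40.
#' @param presynSizeRange presynaptic site size range in voxels; default
#'   450-3000 (above the 400 gate).
#' @param nPostsynApposed number of postsynaptic sites apposed to
#'   (randomly chosen) neuron-1 presynaptic sites; default 15.
#' @param postsynSizeRange postsynaptic size range; default 250-1000, so
#'   even a single overlap voxel meets the 0.1% contact rule.
#' @param apposedOverlapRange contact overlap between apposed pairs in
#'   voxels; default 1-30.
#' @param nNoisePuncta,noiseSizeRange nonspecific puncta in the
#'   presynaptic channel; default 0 puncta of 20-350 voxels.
#' @param backgroundSigma additive Gaussian background noise sd (intensity
#'   units); default 0 (noise-free).
#' @param intensityLevels named intensities for neuron, presyn, postsyn
#'   and noise classes.
#' @param appositionMode `"overlap"` (genuine voxel overlap, default) or
#'   `"touching"` (adjacent but non-overlapping, exercising the contact
#'   dilation switch).
#' @param seed RNG seed; a fixed seed gives byte-identical datasets.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(volumeShape = c(256L, 256L, 256L),
                        nNeurons = 3L,
                        tubeRadius = 4,
                        tubeSteps = 220L,
                        stepLength = 6,
                        gapCount = 2L,
                        gapLength = 10L,
                        nPresynPerNeuron = 40L,
                        presynSizeRange = c(450L, 3000L),
                        nPostsynApposed = 15L,
                        postsynSizeRange = c(250L, 1000L),
                        apposedOverlapRange = c(1L, 30L),
                        nNoisePuncta = 0L,
                        noiseSizeRange = c(20L, 350L),
                        backgroundSigma = 0,
                        intensityLevels = c(neuron = 180, presyn = 220,
                                            postsyn = 220, noise = 200),
                        appositionMode = c("overlap", "touching"),
                        seed = 1L) {
  appositionMode <- match.arg(appositionMode)
  new("PhantomSpec", volumeShape = as.integer(volumeShape),
      nNeurons = as.integer(nNeurons), tubeRadius = as.numeric(tubeRadius),
      tubeSteps = as.integer(tubeSteps), stepLength = as.numeric(stepLength),
      gapCount = as.integer(gapCount), gapLength = as.integer(gapLength),
      nPresynPerNeuron = as.integer(nPresynPerNeuron),
      presynSizeRange = as.integer(presynSizeRange),
      nPostsynApposed = as.integer(nPostsynApposed),
      postsynSizeRange = as.integer(postsynSizeRange),
      apposedOverlapRange = as.integer(apposedOverlapRange),
      nNoisePuncta = as.integer(nNoisePuncta),
      noiseSizeRange = as.integer(noiseSizeRange),
      backgroundSigma = as.numeric(backgroundSigma),
      intensityLevels = intensityLevels,
      appositionMode = appositionMode, seed = as.integer(seed))
}

setValidity("PhantomSpec", function(object) {
  if (any(object@volumeShape < 32L)) return("volumeShape must be >= 32^3")
  if (object@nNeurons < 1L) return("nNeurons must be >= 1")
  if (object@tubeRadius <= 0) return("tubeRadius must be positive")
  if (any(object@presynSizeRange < 1L) ||
      diff(object@presynSizeRange) < 0)
    return("presynSizeRange must be a positive increasing pair")
  if (object@nPostsynApposed > object@nPresynPerNeuron)
    return("nPostsynApposed cannot exceed nPresynPerNeuron")
  TRUE
})

.genError <- function(what) {
  stop("phantom generation failed while placing ", what,
       "; use a larger volume or fewer/smaller objects", call. = FALSE)
}

.unit <- function(v) v / sqrt(sum(v^2))

# bounded-curvature random walk, reflected at the region walls, densified
# to ~unit spacing; returns points (rows z,y,x) and tangents
.phantomWalk <- function(spec, lo, hi) {
  pos <- stats::runif(3, lo + 0.2 * (hi - lo), hi - 0.2 * (hi - lo))
  dir <- .unit(stats::rnorm(3))
  ctrl <- matrix(0, spec@tubeSteps + 1L, 3L)
  ctrl[1L, ] <- pos
  for (i in seq_len(spec@tubeSteps)) {
    dir <- .unit(dir + stats::rnorm(3, sd = 0.35))
    pos <- pos + dir * spec@stepLength
    for (ax in 1:3) {
      if (pos[ax] < lo[ax]) { pos[ax] <- 2 * lo[ax] - pos[ax]; dir[ax] <- -dir[ax] }
      if (pos[ax] > hi[ax]) { pos[ax] <- 2 * hi[ax] - pos[ax]; dir[ax] <- -dir[ax] }
    }
    pos <- pmin(pmax(pos, lo), hi)
    ctrl[i + 1L, ] <- pos
  }
  # densify to ~1-voxel spacing
  pts <- list()
  for (i in seq_len(nrow(ctrl) - 1L)) {
    seg <- ctrl[i + 1L, ] - ctrl[i, ]
    n <- max(1L, ceiling(sqrt(sum(seg^2))))
    tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    pts[[i]] <- cbind(ctrl[i, 1] + tt * seg[1], ctrl[i, 2] + tt * seg[2],
                      ctrl[i, 3] + tt * seg[3])
  }
  pts[[length(pts) + 1L]] <- matrix(ctrl[nrow(ctrl), ], 1L, 3L)
  pts <- do.call(rbind, pts)
  steps <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
  list(points = pts, arclength = c(0, cumsum(steps)))
}

# voxels (0-based coords + linear indices) of an ellipsoid with semi-axes
# (a, b, b), major axis along unit vector u
.ellipsoidVoxels <- function(center, a, b, u, d) {
  r <- ceiling(a) + 1L
  zr <- max(0L, floor(center[1] - r)):min(d[1] - 1L, ceiling(center[1] + r))
  yr <- max(0L, floor(center[2] - r)):min(d[2] - 1L, ceiling(center[2] + r))
  xr <- max(0L, floor(center[3] - r)):min(d[3] - 1L, ceiling(center[3] + r))
  g <- expand.grid(z = zr, y = yr, x = xr, KEEP.OUT.ATTRS = FALSE)
  dz <- g$z - center[1]
  dy <- g$y - center[2]
  dx <- g$x - center[3]
  par <- dz * u[1] + dy * u[2] + dx * u[3]
  perp2 <- pmax(dz^2 + dy^2 + dx^2 - par^2, 0)
  keep <- (par / a)^2 + perp2 / b^2 <= 1
  co <- cbind(g$z[keep], g$y[keep], g$x[keep])
  idx <- co[, 1] + d[1] * (co[, 2] + d[2] * co[, 3]) + 1
  list(coords = co, idx = idx)
}

# TRUE when the candidate voxel set, dilated by `sep`, touches occupied
.tooClose <- function(coords, occupied, d, sep = 2L) {
  off <- .ballOffsets(sep)
  for (r in seq_len(nrow(off))) {
    z <- coords[, 1] + off[r, 1]
    y <- coords[, 2] + off[r, 2]
    x <- coords[, 3] + off[r, 3]
    ok <- z >= 0L & z < d[1] & y >= 0L & y < d[2] & x >= 0L & x < d[3]
    if (any(occupied[z[ok] + d[1] * (y[ok] + d[2] * x[ok]) + 1] != 0))
      return(TRUE)
  }
  FALSE
}

# semi-minor axis for a target ellipsoid volume at aspect ratio rho = a/b
.axisForVolume <- function(nvox, rho) (3 * nvox / (4 * pi * rho))^(1 / 3)

#' Generate a synthetic phantom dataset
#'
#' Builds the three channels (neuron, presynaptic, postsynaptic) plus full
#' ground truth.  All randomness flows from a single RNG stream seeded by
#' `spec@seed`, so a fixed seed gives byte-identical datasets.  Ground
#' truth is recorded during placement, not re-derived.  Placement uses
#' bounded retries; irresolvable crowding raises a generation error.
#'
#' Construction guarantees (checked again by [validateDataset()]): every
#' presynaptic site lies inside a bouton-like swelling of its own neuron
#' (assignment fraction 1), same-channel objects are separated by at least
#' 3 voxels so instances never merge, apposed pairs share the configured
#' overlap, and postsynaptic sites touch no presynaptic site other than
#' their partner.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomDataset-class].
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec@seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  d <- spec@volumeShape
  lv <- spec@intensityLevels
  gtNeurons <- array(0L, d)
  neuronCh <- array(0L, d)
  gtPresyn <- array(0L, d)
  presynCh <- array(0L, d)
  gtPostsyn <- array(0L, d)
  postsynCh <- array(0L, d)
  noiseOcc <- array(FALSE, d)

  maxB <- .axisForVolume(spec@presynSizeRange[2], 1.1)
  margin <- ceiling(spec@tubeRadius + maxB + 6)
  lo <- rep(margin, 3)
  hi <- d - 1 - margin
  if (any(hi - lo < 8)) .genError("neuron tubes (volume too small)")

  # --- neurons: separated random-walk tubes ---------------------------------
  # each neuron's walk is confined to its own slab along the longest axis,
  # with inter-slab clearance large enough that neither tubes, boutons nor
  # apposed sites of different neurons can touch or be bridged at the
  # default 20-voxel gap tolerance
  minSkelSep <- 2 * (spec@tubeRadius + maxB) + 22
  walks <- vector("list", spec@nNeurons)
  axis <- which.max(hi - lo)
  slabW <- (hi[axis] - lo[axis] - (spec@nNeurons - 1) * minSkelSep) /
    spec@nNeurons
  if (spec@nNeurons > 1L && slabW < 4 * spec@tubeRadius)
    .genError("neuron tubes (slabs too thin)")
  sphereOff <- .ballOffsets(spec@tubeRadius)
  sphereLin <- sphereOff[, 1] + d[1] * (sphereOff[, 2] + d[2] * sphereOff[, 3])

  # Each neuron gets a walk plus its presynaptic sites; if a walk curls so
  # tightly that its surface cannot host all sites, the neuron's stamps are
  # rolled back and a fresh walk is drawn.
  siteId <- 0L
  siteInfo <- list()
  for (k in seq_len(spec@nNeurons)) {
    lk <- lo
    hk <- hi
    if (spec@nNeurons > 1L) {
      lk[axis] <- lo[axis] + (k - 1) * (slabW + minSkelSep)
      hk[axis] <- lk[axis] + slabW
    }
    neuronDone <- FALSE
    for (walkAtt in seq_len(10L)) {
      w <- .phantomWalk(spec, lk, hk)
      pts <- round(w$points)
      ctr <- pts[, 1] + d[1] * (pts[, 2] + d[2] * pts[, 3]) + 1
      tubeIdx <- unique(as.vector(outer(sphereLin, ctr, `+`)))
      gtNeurons[tubeIdx] <- k
      L <- max(w$arclength)
      startId <- siteId
      placedSites <- list()
      ok <- TRUE
      for (s in seq_len(spec@nPresynPerNeuron)) {
        placed <- FALSE
        for (att in seq_len(400L)) {
          target <- round(stats::runif(1, spec@presynSizeRange[1] + 60,
                                       spec@presynSizeRange[2] - 200))
          rho <- stats::runif(1, 1.1, 1.4)
          b <- .axisForVolume(target, rho)
          a <- rho * b
          arc <- stats::runif(1, a + 2, L - a - 2)
          i <- findInterval(arc, w$arclength)
          p0 <- w$points[i, ]
          tangent <- .unit(w$points[min(i + 2L, nrow(w$points)), ] -
                             w$points[max(i - 2L, 1L), ])
          rv <- .unit(stats::rnorm(3))
          perp <- rv - sum(rv * tangent) * tangent
          if (sqrt(sum(perp^2)) < 1e-3) next
          perp <- .unit(perp)
          center <- p0 + perp * spec@tubeRadius
          ev <- .ellipsoidVoxels(center, a, b, tangent, d)
          n <- nrow(ev$coords)
          if (n < spec@presynSizeRange[1] || n > spec@presynSizeRange[2]) next
          if (any(ev$coords < 2L) || any(sweep(ev$coords, 2L, d - 3L) > 0L))
            next
          if (.tooClose(ev$coords, gtPresyn, d, 2L)) next
          siteId <- siteId + 1L
          gtPresyn[ev$idx] <- siteId
          presynCh[ev$idx] <- lv[["presyn"]]
          gtNeurons[ev$idx] <- k        # bouton swelling belongs to neuron k
          siteInfo[[siteId]] <- list(id = siteId, neuron = k, center = center,
                                     a = a, b = b, u = tangent, arc = arc,
                                     anchor = p0, perp = perp, n = n)
          placedSites[[length(placedSites) + 1L]] <- ev$idx
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        walks[[k]] <- w
        neuronDone <- TRUE
        break
      }
      # roll back this neuron entirely and try a new walk
      for (idx in placedSites) {
        gtPresyn[idx] <- 0L
        presynCh[idx] <- 0L
      }
      gtNeurons[gtNeurons == k] <- 0L
      siteInfo <- siteInfo[seq_len(startId)]
      siteId <- startId
    }
    if (!neuronDone)
      .genError(sprintf("presynaptic sites on neuron %d", k))
  }

  # --- neuron channel: tubes with labeling gaps, plus boutons ---------------
  for (k in seq_len(spec@nNeurons)) {
    w <- walks[[k]]
    L <- max(w$arclength)
    gaps <- numeric(0)
    sitesK <- Filter(function(si) si$neuron == k, siteInfo)
    arcs <- vapply(sitesK, function(si) si$arc, numeric(1))
    amax <- vapply(sitesK, function(si) si$a, numeric(1))
    if (spec@gapCount > 0L) {
      for (gidx in seq_len(spec@gapCount)) {
        placed <- FALSE
        for (att in seq_len(400L)) {
          g <- stats::runif(1, 0.15 * L, 0.85 * L - spec@gapLength)
          gc <- g + spec@gapLength / 2
          # a bouton must never fully cover the zeroed stretch
          if (length(arcs) && any(abs(gc - arcs) <= amax - 2)) next
          if (length(gaps) && any(abs(gc - gaps) <
                                    3 * (spec@gapLength + 2 * spec@tubeRadius)))
            next
          gaps <- c(gaps, gc)
          placed <- TRUE
          break
        }
        if (!placed) .genError(sprintf("labeling gap %d on neuron %d", gidx, k))
      }
    }
    # stamps removed over [gap - r, gap + len + r] so the surface gap is
    # about gapLength
    keep <- rep(TRUE, nrow(w$points))
    for (gc in gaps) {
      g0 <- gc - spec@gapLength / 2 - spec@tubeRadius
      g1 <- gc + spec@gapLength / 2 + spec@tubeRadius
      keep <- keep & !(w$arclength >= g0 & w$arclength <= g1)
    }
    pts <- round(w$points[keep, , drop = FALSE])
    ctr <- pts[, 1] + d[1] * (pts[, 2] + d[2] * pts[, 3]) + 1
    idx <- unique(as.vector(outer(sphereLin, ctr, `+`)))
    neuronCh[idx] <- lv[["neuron"]]
  }
  # boutons are part of the neuron's label signal
  neuronCh[gtPresyn > 0L] <- lv[["neuron"]]

  # --- apposed postsynaptic sites -------------------------------------------
  connections <- data.frame(pre_id = integer(0), post_id = integer(0),
                            overlap_voxels = integer(0))
  if (spec@nPostsynApposed > 0L) {
    n1sites <- Filter(function(si) si$neuron == 1L, siteInfo)
    # candidate partners in random order; crowded candidates are skipped in
    # favor of the next one
    candidates <- sample(vapply(n1sites, function(si) si$id, integer(1)))
    postId <- 0L
    for (pid in candidates) {
      if (postId >= spec@nPostsynApposed) break
      si <- siteInfo[[pid]]
      placed <- FALSE
      for (att in seq_len(400L)) {
        target <- round(stats::runif(1, spec@postsynSizeRange[1] + 30,
                                     spec@postsynSizeRange[2] - 60))
        rho <- stats::runif(1, 1.05, 1.3)
        bq <- .axisForVolume(target, rho)
        aq <- rho * bq
        jitter <- .unit(si$perp + stats::rnorm(3, sd = 0.2))
        dir <- jitter
        uq <- si$u                       # roughly parallel to the tube
        found <- NULL
        for (off in seq(si$b + bq + 2, max(si$b - 2, 1), by = -0.25)) {
          cq <- si$center + dir * off
          ev <- .ellipsoidVoxels(cq, aq, bq, uq, d)
          ovl <- sum(gtPresyn[ev$idx] == pid)
          if (spec@appositionMode == "overlap") {
            if (ovl >= spec@apposedOverlapRange[1] &&
                ovl <= spec@apposedOverlapRange[2]) { found <- list(ev, ovl); break }
            if (ovl > spec@apposedOverlapRange[2]) break
          } else {
            if (ovl >= 1L) break
            prev <- list(ev, 0L)
            found <- prev                 # last non-overlapping offset
          }
        }
        if (is.null(found)) next
        ev <- found[[1]]
        ovl <- found[[2]]
        n <- nrow(ev$coords)
        if (n < spec@postsynSizeRange[1] || n > spec@postsynSizeRange[2]) next
        if (any(ev$coords < 2L) || any(sweep(ev$coords, 2L, d - 3L) > 0L)) next
        other <- gtPresyn[ev$idx]
        if (any(!other %in% c(0L, pid))) next  # touch only the partner
        if (.tooClose(ev$coords, gtPostsyn, d, 2L)) next
        # the 0.1% rule must fire even for the smallest contact
        if (spec@appositionMode == "overlap" && ovl / n < 0.001) next
        postId <- postId + 1L
        gtPostsyn[ev$idx] <- postId
        postsynCh[ev$idx] <- lv[["postsyn"]]
        connections <- rbind(connections,
                             data.frame(pre_id = pid, post_id = postId,
                                        overlap_voxels = as.integer(ovl)))
        placed <- TRUE
        break
      }
    }
    if (postId < spec@nPostsynApposed)
      .genError(sprintf("apposed postsynaptic sites (%d of %d placed)",
                        postId, spec@nPostsynApposed))
  }

  # --- nonspecific puncta in the presynaptic channel ------------------------
  if (spec@nNoisePuncta > 0L) {
    for (j in seq_len(spec@nNoisePuncta)) {
      placed <- FALSE
      for (att in seq_len(400L)) {
        target <- round(stats::runif(1, spec@noiseSizeRange[1] + 5,
                                     spec@noiseSizeRange[2] - 15))
        rho <- stats::runif(1, 1.0, 1.2)
        b <- .axisForVolume(target, rho)
        u <- .unit(stats::rnorm(3))
        center <- stats::runif(3, b + 2, d - b - 3)
        ev <- .ellipsoidVoxels(center, rho * b, b, u, d)
        n <- nrow(ev$coords)
        if (n < spec@noiseSizeRange[1] || n > spec@noiseSizeRange[2]) next
        occ <- gtPresyn[ev$idx] > 0L | noiseOcc[ev$idx]
        if (any(occ)) next
        if (.tooClose(ev$coords, gtPresyn, d, 2L)) next
        if (.tooClose(ev$coords, noiseOcc, d, 2L)) next
        noiseOcc[ev$idx] <- TRUE
        presynCh[ev$idx] <- lv[["noise"]]
        placed <- TRUE
        break
      }
      if (!placed) .genError(sprintf("noise punctum %d", j))
    }
  }

  if (spec@backgroundSigma > 0) {
    addNoise <- function(ch) {
      v <- as.integer(pmax(round(as.numeric(ch) +
                                   stats::rnorm(length(ch),
                                                sd = spec@backgroundSigma)), 0))
      array(v, d)
    }
    neuronCh <- addNoise(neuronCh)
    presynCh <- addNoise(presynCh)
    postsynCh <- addNoise(postsynCh)
  }

  assignments <- data.frame(
    site_id = vapply(siteInfo, function(si) si$id, integer(1)),
    neuron_id = vapply(siteInfo, function(si) si$neuron, integer(1)),
    role = "presynaptic",
    voxel_count = vapply(siteInfo, function(si) si$n, integer(1)))

  new("PhantomDataset",
      neuronChannel = VoxelVolume(neuronCh),
      presynChannel = VoxelVolume(presynCh),
      postsynChannel = VoxelVolume(postsynCh),
      gtNeurons = LabelVolume(gtNeurons),
      gtPresyn = LabelVolume(gtPresyn),
      gtPostsyn = LabelVolume(gtPostsyn),
      assignments = assignments,
      connections = connections,
      spec = spec)
}

setMethod("show", "PhantomDataset", function(object) {
  cat("PhantomDataset",
      paste(dim(object@neuronChannel@.Data), collapse = " x "), "\n")
  cat("  neurons:", max(object@gtNeurons@.Data, 0L),
      " presyn sites:", max(object@gtPresyn@.Data, 0L),
      " postsyn sites:", max(object@gtPostsyn@.Data, 0L),
      " gt connections:", nrow(object@connections), "\n")
})

#' Validate a phantom dataset against its invariants
#'
#' Re-checks every ground-truth invariant directly on the emitted volumes:
#' table/label consistency, per-site assignment overlap at least the
#' configured fraction, connection overlaps at least one voxel and at
#' least the contact fraction of the postsynaptic site, postsynaptic
#' sites touching only their partner, and site sizes within the spec
#' ranges.  Fails loudly, naming object ids.
#'
#' @param d a [PhantomDataset-class].
#' @param cfg a [PipelineConfig-class] providing the fractions to check
#'   against.
#' @return invisibly a list of the measured quantities.
#' @export
validateDataset <- function(d, cfg = pipelineConfig()) {
  stopifnot(is(d, "PhantomDataset"))
  spec <- d@spec
  pre <- d@gtPresyn@.Data
  post <- d@gtPostsyn@.Data
  npre <- max(pre, 0L)
  npost <- max(post, 0L)
  preSize <- tabulate(pre, nbins = npre)
  if (!identical(sort(d@assignments$site_id), seq_len(npre)))
    stop("assignment table ids do not match the presynaptic label volume",
         call. = FALSE)
  if (any(preSize == 0L))
    stop("empty presynaptic labels: ",
         paste(which(preSize == 0L), collapse = ", "), call. = FALSE)
  bad <- which(preSize < spec@presynSizeRange[1] |
                 preSize > spec@presynSizeRange[2])
  if (length(bad))
    stop("presynaptic sites outside the size range: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # assignment invariant
  for (k in sort(unique(d@assignments$neuron_id))) {
    ids <- d@assignments$site_id[d@assignments$neuron_id == k]
    inside <- tabulate(pre[d@gtNeurons@.Data == k], nbins = npre)
    frac <- inside[ids] / preSize[ids]
    viol <- ids[frac < cfg@assignmentFraction]
    if (length(viol))
      stop(sprintf("presynaptic sites not assignable to neuron %d: %s", k,
                   paste(viol, collapse = ", ")), call. = FALSE)
  }
  # connection invariants
  ov <- .overlapPairs(post, pre)
  tab <- d@connections
  if (spec@appositionMode == "overlap") {
    wanted <- paste(tab$post_id, tab$pre_id)
    got <- paste(ov$a, ov$b)
    if (!setequal(wanted, got))
      stop("connection table does not match measured overlaps; pairs differ: ",
           paste(union(setdiff(wanted, got), setdiff(got, wanted)),
                 collapse = "; "), call. = FALSE)
    postSize <- tabulate(post, nbins = npost)
    m <- match(paste(tab$post_id, tab$pre_id), got)
    meas <- ov$overlap[m]
    if (!all(meas == tab$overlap_voxels))
      stop("recorded connection overlaps differ from measurement",
           call. = FALSE)
    fr <- meas / postSize[tab$post_id]
    viol <- tab$post_id[fr < cfg@contactFraction]
    if (length(viol))
      stop("connections below the contact fraction for postsynaptic sites: ",
           paste(viol, collapse = ", "), call. = FALSE)
  } else if (nrow(ov))
    stop("touching-mode dataset has overlapping apposed pairs", call. = FALSE)
  invisible(list(n_presyn = npre, n_postsyn = npost,
                 n_connections = nrow(tab)))
}
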