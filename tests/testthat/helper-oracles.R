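# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different algorithms from the package internals.

# connected components by min-label propagation: every foreground voxel
# starts with its own linear index as label; labels are repeatedly replaced
# by the minimum over adjacent foreground voxels until stable
propagationComponents <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  repeat {
    old <- lab
    for (r in seq_len(nrow(offs))) {
      o <- unlist(offs[r, ])
      az <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
      ay <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
      ax <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
      A <- lab[az, ay, ax, drop = FALSE]
      B <- lab[az + o[1], ay + o[2], ax + o[3], drop = FALSE]
      sel <- A > 0 & B > 0 & B < A
      A[sel] <- B[sel]
      lab[az, ay, ax] <- A
    }
    if (identical(old, lab)) break
  }
  # dense relabel in order of first (raster) appearance
  ids <- unique(lab[lab > 0])
  ids <- ids[order(match(ids, lab))]
  out <- array(0L, d)
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# canonical signature of a labeling's partition (label values ignored)
partitionSignature <- function(labArr) {
  f <- split(which(labArr > 0), labArr[labArr > 0])
  f <- lapply(f, sort)
  f[order(vapply(f, `[`, numeric(1), 1))]
}

# exhaustive Otsu scan over all integer thresholds (foreground = v >= t)
otsuScanOracle <- function(vals) {
  best <- -Inf
  bestT <- NA
  for (t in seq(min(vals) + 1, max(vals))) {
    b <- vals[vals < t]
    f <- vals[vals >= t]
    if (!length(b) || !length(f)) next
    w0 <- length(b) / length(vals)
    bcv <- w0 * (1 - w0) * (mean(b) - mean(f))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      bestT <- t
    }
  }
  bestT
}

# Li minimum cross-entropy threshold by fixed-point iteration to 1e-6
liFixedPointOracle <- function(vals) {
  t <- mean(vals)
  repeat {
    mb <- mean(vals[vals < t])
    mf <- mean(vals[vals >= t])
    if (is.nan(mb)) mb <- 0
    tn <- (mf - mb) / (log(max(mf, 1e-12)) - log(max(mb, 1e-12)))
    if (abs(tn - t) < 1e-6) return(tn)
    t <- tn
  }
}

# solid axis-aligned tube (cylinder along x) as a logical array
solidTube <- function(d, z0, y0, xRange, radius) {
  a <- array(FALSE, d)
  for (x in xRange) {
    for (z in max(1, z0 - radius):min(d[1], z0 + radius)) {
      for (y in max(1, y0 - radius):min(d[2], y0 + radius)) {
        if ((z - z0)^2 + (y - y0)^2 <= radius^2) a[z, y, x] <- TRUE
      }
    }
  }
  a
}

# sphere voxels stamped into an array
stampSphere <- function(a, center, radius, value = TRUE) {
  d <- dim(a)
  zr <- max(1, center[1] - radius):min(d[1], center[1] + radius)
  yr <- max(1, center[2] - radius):min(d[2], center[2] + radius)
  xr <- max(1, center[3] - radius):min(d[3], center[3] + radius)
  for (z in zr) for (y in yr) for (x in xr)
    if (sum((c(z, y, x) - center)^2) <= radius^2) a[z, y, x] <- value
  a
}

# a small marker volume with well-separated ellipsoidal sites plus
# sub-gate specks; returns the volume and the ground-truth site count
punctaFixture <- function(d = c(96L, 96L, 96L), nSites = 8L, nSpecks = 30L,
                          siteSize = c(600L, 1500L), speckSize = c(30L, 300L),
                          intensity = c(site = 220, speck = 200),
                          seed = 99L) {
  withr::local_seed(seed)
  arr <- array(0L, d)
  gt <- array(0L, d)
  placed <- 0L
  guard <- array(FALSE, d)
  tryPlace <- function(sizeRange, label, value) {
    for (att in 1:200) {
      target <- round(runif(1, sizeRange[1], sizeRange[2]))
      rho <- runif(1, 1.05, 1.3)
      b <- (3 * target / (4 * pi * rho))^(1 / 3)
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      ctr <- runif(3, rho * b + 3, d - rho * b - 4)
      ev <- SynConnect:::.ellipsoidVoxels(ctr, rho * b, b, u, d)
      if (nrow(ev$coords) < sizeRange[1] || nrow(ev$coords) > sizeRange[2])
        next
      # 3-voxel clearance so instances never merge
      if (SynConnect:::.tooClose(ev$coords, guard, d, 2L)) next
      arr[ev$idx] <<- as.integer(value)
      guard[ev$idx] <<- TRUE
      if (label > 0L) gt[ev$idx] <<- label
      return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(nSites))
    if (!tryPlace(siteSize, i, intensity[["site"]]))
      stop("fixture placement failed")
  for (i in seq_len(nSpecks))
    if (!tryPlace(speckSize, 0L, intensity[["speck"]]))
      stop("fixture placement failed")
  list(volume = VoxelVolume(arr), gt = LabelVolume(gt), nSites = nSites)
}

# small, fast phantom used by many tests
smallPhantomSpec <- function(seed = 3L, ...) {
  phantomSpec(volumeShape = c(128L, 128L, 128L), nNeurons = 2L,
              tubeSteps = 60L, nPresynPerNeuron = 10L, nPostsynApposed = 5L,
              presynSizeRange = c(450L, 1500L), seed = seed, ...)
}

w2Channels <- function(d) {
  list(presyn = d@presynChannel,
       neuron1_mask = BinaryMask(voxelData(d@gtNeurons) == 1L),
       postsyn = d@postsynChannel)
}

# memoized expensive fixtures shared across test files
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}
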