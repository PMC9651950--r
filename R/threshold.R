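#' Threshold specification constructor
#'
#' @param method `"otsu"`, `"li"`, or `"manual"`.
#' @param value manual threshold value; required iff `method = "manual"`.
#' @return a [ThresholdSpec-class].
#' @export
thresholdSpec <- function(method = c("otsu", "li", "manual"), value = NA_real_) {
  method <- match.arg(method)
  if (method == "manual" && is.na(value))
    stop("manual thresholding requires a value", call. = FALSE)
  new("ThresholdSpec", method = method, value = as.numeric(value))
}

# histogram over integer gray levels (8/16-bit) or 256 uniform bins for
# real-valued volumes; returns bin values and counts
.grayHistogram <- function(vals) {
  if (is.integer(vals) || all(vals == round(vals))) {
    mx <- max(vals)
    levels <- if (mx <= 255) 0:255 else 0:65535
    counts <- tabulate(as.integer(vals) + 1L, nbins = length(levels))
    list(values = as.numeric(levels), counts = counts)
  } else {
    rng <- range(vals)
    edges <- seq(rng[1], rng[2], length.out = 257L)
    idx <- findInterval(vals, edges, rightmost.closed = TRUE)
    list(values = edges[-length(edges)],
         counts = tabulate(idx, nbins = 256L))
  }
}

# Otsu: threshold t (foreground = value >= t) maximizing the between-class
# variance, exhaustive over all histogram levels, lowest t on ties
.otsuThreshold <- function(vals) {
  h <- .grayHistogram(vals)
  n <- sum(h$counts)
  # candidate t = h$values[k]: background is bins < k
  cb <- cumsum(h$counts)                 # counts <= bin k
  sb <- cumsum(h$counts * h$values)
  total <- sb[length(sb)]
  k <- seq_along(h$values)[-1]           # background nonempty candidates
  w0 <- cb[k - 1L] / n
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- sb[k - 1L] / cb[k - 1L]
  mu1 <- (total - sb[k - 1L]) / (n - cb[k - 1L])
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- which.max(bcv)                 # first (lowest) maximum
  h$values[k[best]]
}

# Li: iterative minimum cross-entropy threshold, run to |t' - t| < 1e-6;
# the log-mean update assumes non-negative grays, so data are shifted only
# when negative values are present
.liThreshold <- function(vals) {
  s <- min(min(vals), 0)
  w <- as.numeric(vals) - s
  t <- mean(w)
  eps <- 1e-9 * max(mean(w), 1)
  for (i in seq_len(500L)) {
    back <- w[w < t]
    fore <- w[w >= t]
    mb <- if (length(back)) mean(back) else 0
    mf <- if (length(fore)) mean(fore) else 0
    mb <- max(mb, eps)
    mf <- max(mf, eps)
    tNew <- if (abs(mf - mb) < eps) t else (mf - mb) / (log(mf) - log(mb))
    if (abs(tNew - t) < 1e-6) { t <- tNew; break }
    t <- tNew
  }
  t + s
}

#' Compute a global intensity threshold
#'
#' Otsu (maximal between-class variance over all candidate gray levels, on a
#' 256-bin histogram for 8-bit and a 65,536-bin histogram for 16-bit input),
#' Li (iterative minimum cross-entropy), or the manual value.  Ties are
#' broken toward the lowest threshold achieving the optimum.  The
#' thresholding rule everywhere in this package is `foreground = value >=
#' threshold`.
#'
#' @param v a [VoxelVolume-class].
#' @param spec a [ThresholdSpec-class].
#' @return the scalar threshold.
#' @export
computeThreshold <- function(v, spec = thresholdSpec("otsu")) {
  stopifnot(is(v, "VoxelVolume"), is(spec, "ThresholdSpec"))
  if (spec@method == "manual") return(spec@value)
  vals <- as.vector(v@.Data)
  if (length(unique(vals)) < 2L)
    stop("volume is constant; automatic (otsu/li) thresholding is ",
         "degenerate - supply a manual threshold", call. = FALSE)
  switch(spec@method, otsu = .otsuThreshold(vals), li = .liThreshold(vals))
}

#' Apply an intensity threshold
#'
#' `mask = (v >= t)`; monotone in `t`: a higher threshold always yields a
#' subset of the lower threshold's foreground.
#'
#' @param v a [VoxelVolume-class].
#' @param t scalar threshold.
#' @return a [BinaryMask-class].
#' @export
applyThreshold <- function(v, t) {
  stopifnot(is(v, "VoxelVolume"), is.finite(t))
  BinaryMask(v@.Data >= t, v@voxelSize, v@origin)
}
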