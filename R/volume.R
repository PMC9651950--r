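#' Construct a VoxelVolume
#'
#' @param data 3D array (z,y,x axis order).
#' @param voxelSize voxel size in nm along z,y,x.
#' @param origin 0-based z,y,x offset inside the parent grid.
#' @return A [VoxelVolume-class] object.
#' @examples
#' v <- VoxelVolume(array(0L, c(4, 8, 8)), voxelSize = c(180, 104, 104))
#' dim(v)
#' @export
VoxelVolume <- function(data, voxelSize = c(1, 1, 1), origin = c(0L, 0L, 0L)) {
  if (is.null(dim(data))) stop("data must be a 3D array", call. = FALSE)
  new("VoxelVolume", data, voxelSize = as.numeric(voxelSize),
      origin = as.integer(origin))
}

#' Construct a BinaryMask
#'
#' Non-logical input is interpreted as foreground where nonzero.
#'
#' @inheritParams VoxelVolume
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(data, voxelSize = c(1, 1, 1), origin = c(0L, 0L, 0L)) {
  if (!is.logical(data)) {
    d <- dim(data)
    data <- array(as.vector(data) != 0, d)
  }
  new("BinaryMask", data, voxelSize = as.numeric(voxelSize),
      origin = as.integer(origin))
}

#' Construct a LabelVolume
#'
#' @inheritParams VoxelVolume
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(data, voxelSize = c(1, 1, 1), origin = c(0L, 0L, 0L)) {
  if (!is.integer(data)) {
    d <- dim(data)
    data <- array(as.integer(data), d)
  }
  new("LabelVolume", data, voxelSize = as.numeric(voxelSize),
      origin = as.integer(origin))
}

#' @rdname voxelSize
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel size accessor
#'
#' @param x a [VoxelVolume-class] (or subclass).
#' @return numeric(3), voxel size in nm along z,y,x.
#' @export
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)

#' @rdname origin
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Origin accessor
#'
#' @param x a [VoxelVolume-class] (or subclass).
#' @return integer(3), 0-based z,y,x offset within the parent grid.
#' @export
setMethod("origin", "VoxelVolume", function(x) x@origin)

#' @rdname voxelData
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Extract the bare data array
#'
#' @param x a [VoxelVolume-class] (or subclass).
#' @return the underlying 3D array, stripped of class and metadata.
#' @export
setMethod("voxelData", "VoxelVolume", function(x) {
  a <- x@.Data
  dim(a) <- dim(x@.Data)
  a
})

#' Number of labels in a LabelVolume
#'
#' @param x a [LabelVolume-class].
#' @return the largest label id (labels are contiguous 1..K after
#'   relabeling operations).
#' @export
nLabels <- function(x) {
  stopifnot(is(x, "LabelVolume"))
  if (length(x@.Data) == 0L) return(0L)
  max(x@.Data, 0L)
}

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@.Data)
  cat(class(object), sprintf("%d x %d x %d (z,y,x)\n", d[1], d[2], d[3]))
  cat("  voxel size (nm):", paste(format(object@voxelSize), collapse = " x "),
      "\n")
  cat("  origin (0-based):", paste(object@origin, collapse = ","), "\n")
  if (is(object, "BinaryMask")) {
    cat("  foreground voxels:", sum(object@.Data), "\n")
  } else if (is(object, "LabelVolume")) {
    cat("  labels:", nLabels(object), "\n")
  } else {
    rng <- range(object@.Data)
    cat("  intensity range:", format(rng[1]), "-", format(rng[2]), "\n")
  }
})

# --- internal box helpers ----------------------------------------------------
# user-facing boxes are 0-based inclusive (zmin, zmax, ymin, ymax, xmin, xmax)

.checkBox <- function(bbox, shape = NULL) {
  if (length(bbox) != 6L || anyNA(bbox))
    stop("bbox must be (zmin, zmax, ymin, ymax, xmin, xmax)", call. = FALSE)
  bbox <- as.integer(bbox)
  lo <- bbox[c(1, 3, 5)]
  hi <- bbox[c(2, 4, 6)]
  if (any(lo > hi))
    stop("bbox must have min <= max on every axis", call. = FALSE)
  if (!is.null(shape) && (any(lo < 0L) || any(hi > shape - 1L))) {
    clipLo <- pmax(lo, 0L)
    clipHi <- pmin(hi, shape - 1L)
    stop(sprintf(
      "bbox out of bounds for volume of shape (%s); clipped extent would be (%s)",
      paste(shape, collapse = ","),
      paste(rbind(clipLo, clipHi), collapse = ",")), call. = FALSE)
  }
  bbox
}

.sliceBox <- function(data, bbox) {
  data[(bbox[1] + 1L):(bbox[2] + 1L),
       (bbox[3] + 1L):(bbox[4] + 1L),
       (bbox[5] + 1L):(bbox[6] + 1L), drop = FALSE]
}

#' @rdname cropRoi
#' @export
setGeneric("cropRoi", function(x, bbox) standardGeneric("cropRoi"))

#' Crop a region of interest
#'
#' Extracts the inclusive 0-based voxel box `(zmin, zmax, ymin, ymax, xmin,
#' xmax)`; the result's origin is advanced by `(zmin, ymin, xmin)` so global
#' coordinates can be recovered.
#'
#' @param x a [VoxelVolume-class], [BinaryMask-class] or [LabelVolume-class].
#' @param bbox integer(6), inclusive 0-based box.
#' @return an object of the same class as `x`.
#' @examples
#' v <- VoxelVolume(array(seq_len(1000), c(10, 10, 10)))
#' dim(cropRoi(v, c(2, 4, 2, 4, 2, 4)))  # 3 x 3 x 3
#' @export
setMethod("cropRoi", "VoxelVolume", function(x, bbox) {
  bbox <- .checkBox(bbox, dim(x@.Data))
  out <- x
  out@.Data <- .sliceBox(x@.Data, bbox)
  out@origin <- x@origin + as.integer(bbox[c(1, 3, 5)])
  validObject(out)
  out
})

#' @rdname maxProjection
#' @export
setGeneric("maxProjection", function(x, axis = c("z", "y", "x"))
  standardGeneric("maxProjection"))

#' Maximum intensity projection
#'
#' Collapses one axis by taking the per-pixel maximum, the standard MIP used
#' to inspect volumes and to pick mask thresholds.
#'
#' @param x a [VoxelVolume-class] or [BinaryMask-class].
#' @param axis axis to collapse: `"z"` (default), `"y"` or `"x"`.
#' @return a 2D matrix; for `axis = "z"` its dimensions are (y, x).
#' @export
setMethod("maxProjection", "VoxelVolume", function(x, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  margin <- switch(axis, z = c(2, 3), y = c(1, 3), x = c(1, 2))
  apply(x@.Data, margin, max)
})

#' Subtract channel cross-talk
#'
#' `out = max(a - factor * b, 0)`, clamping at zero and preserving integer
#' storage by saturating cast, used to remove bleed-through of one
#' fluorescence channel into another.
#'
#' @param a,b [VoxelVolume-class] objects of identical shape.
#' @param factor non-negative bleed-through factor.
#' @return a [VoxelVolume-class] with `a`'s metadata.
#' @export
subtractCrosstalk <- function(a, b, factor) {
  stopifnot(is(a, "VoxelVolume"), is(b, "VoxelVolume"))
  if (!identical(dim(a@.Data), dim(b@.Data)))
    stop("subtractCrosstalk: volumes must have identical shapes",
         call. = FALSE)
  if (!is.finite(factor) || factor < 0)
    stop("factor must be a non-negative number", call. = FALSE)
  out <- pmax(as.numeric(a@.Data) - factor * as.numeric(b@.Data), 0)
  if (is.integer(a@.Data)) out <- as.integer(round(out))
  res <- a
  res@.Data <- array(out, dim(a@.Data))
  res
}

# translate a volume's contents by an integer 0-based offset within the same
# shape (used by equivariance tests and the phantom module)
.translateArray <- function(a, shift) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else if (is.integer(a)) 0L else 0, d)
  src <- lapply(1:3, function(k) {
    if (shift[k] >= 0) seq_len(d[k] - shift[k]) else (1 - shift[k]):d[k]
  })
  dst <- lapply(1:3, function(k) {
    if (shift[k] >= 0) (1 + shift[k]):d[k] else seq_len(d[k] + shift[k])
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
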