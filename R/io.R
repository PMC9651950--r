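#' @importFrom jsonlite read_json write_json
#' @importFrom utils write.table read.csv
NULL

.ATTR_FILE <- "attributes.json"

.sidecarAttrs <- function(x, kind) {
  list(voxel_size_nm = as.numeric(x@voxelSize),
       axis_order = "zyx",
       origin_voxel = as.integer(x@origin),
       kind = kind)
}

.volumeKind <- function(x) {
  if (is(x, "BinaryMask")) "mask"
  else if (is(x, "LabelVolume")) "labels"
  else if (is.double(x@.Data)) "float"
  else "intensity"
}

# voxel size from an attribute list; the canonical key voxel_size_nm is
# z,y,x; the N5-style pixelResolution key is x,y,z and gets reversed
.voxelSizeFromAttrs <- function(attrs, default = c(1, 1, 1)) {
  if (!is.null(attrs$voxel_size_nm)) return(as.numeric(unlist(attrs$voxel_size_nm)))
  if (!is.null(attrs$pixelResolution)) {
    pr <- attrs$pixelResolution
    if (is.list(pr) && !is.null(pr$dimensions)) pr <- pr$dimensions
    return(rev(as.numeric(unlist(pr))))
  }
  as.numeric(default)
}

.wrapVolume <- function(data, kind, voxelSize, origin = c(0L, 0L, 0L)) {
  switch(kind,
    mask = BinaryMask(data != 0, voxelSize, origin),
    labels = LabelVolume(data, voxelSize, origin),
    VoxelVolume(data, voxelSize, origin))
}

# ---- TIFF series ------------------------------------------------------------

.writeTiffSeries <- function(x, path) {
  kind <- .volumeKind(x)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop("cannot create TIFF series directory: ", path, call. = FALSE)
  a <- x@.Data
  if (kind == "mask") {
    a <- array(ifelse(a, 255L, 0L), dim(a))  # uint8 {0,255} viewer dialect
  }
  mx <- if (length(a)) max(a) else 0
  if (kind == "float") {
    bits <- 32L
    scale <- 1
  } else {
    if (min(a) < 0) stop("TIFF series requires non-negative values", call. = FALSE)
    if (mx > 65535)
      stop("values exceed 16-bit TIFF range; use format = 'chunked_store'",
           call. = FALSE)
    bits <- if (mx > 255) 16L else 8L
    scale <- if (bits == 8L) 255 else 65535
  }
  d <- dim(a)
  for (z in seq_len(d[1])) {
    slice <- matrix(as.numeric(a[z, , ]) / scale, d[2], d[3])
    tiff::writeTIFF(slice, file.path(path, sprintf("slice_%05d.tif", z - 1L)),
                    bits.per.sample = bits)
  }
  attrs <- c(.sidecarAttrs(x, kind), list(dtype = if (kind == "float")
    "float32" else sprintf("uint%d", bits), n_slices = d[1]))
  jsonlite::write_json(attrs, file.path(path, .ATTR_FILE), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

.readTiffSeries <- function(path, voxelSize) {
  files <- sort(list.files(path, pattern = "\\.tif{1,2}$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no TIFF slices found in ", path, call. = FALSE)
  attrs <- list()
  af <- file.path(path, .ATTR_FILE)
  if (file.exists(af)) attrs <- jsonlite::read_json(af)
  kind <- if (!is.null(attrs$kind)) attrs$kind else "intensity"
  slices <- vector("list", length(files))
  ref <- NULL
  for (i in seq_along(files)) {
    s <- tiff::readTIFF(files[i], as.is = TRUE)
    if (is.null(ref)) ref <- dim(s)
    if (!identical(dim(s), ref))
      stop(sprintf("inconsistent slice shape in %s (expected %s, got %s)",
                   basename(files[i]), paste(ref, collapse = "x"),
                   paste(dim(s), collapse = "x")), call. = FALSE)
    slices[[i]] <- s
  }
  isFloat <- identical(kind, "float") || is.double(slices[[1]])
  a <- array(if (isFloat) 0 else 0L, c(length(files), ref[1], ref[2]))
  for (i in seq_along(slices)) a[i, , ] <- slices[[i]]
  vs <- .voxelSizeFromAttrs(attrs, voxelSize)
  org <- if (!is.null(attrs$origin_voxel))
    as.integer(unlist(attrs$origin_voxel)) else c(0L, 0L, 0L)
  .wrapVolume(a, kind, vs, org)
}

# ---- chunked store ----------------------------------------------------------
# N5-like directory layout: attributes.json plus chunks/<cz>_<cy>_<cx>.bin,
# raw little-endian, written in R array (z-fastest) order within each chunk;
# boundary chunks are clipped.

.dtypeOf <- function(x, kind) {
  if (kind == "mask") "uint8" else if (kind == "float") "float64" else "int32"
}

.chunkRanges <- function(extent, chunk) {
  starts <- seq.int(0L, extent - 1L, by = chunk)
  lapply(starts, function(s) c(s, min(s + chunk, extent) - 1L))
}

.writeChunkedStore <- function(x, path, chunkShape = c(128L, 128L, 128L)) {
  kind <- .volumeKind(x)
  dtype <- .dtypeOf(x, kind)
  dir.create(file.path(path, "chunks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(path, "chunks")))
    stop("cannot create chunked store at: ", path, call. = FALSE)
  a <- x@.Data
  if (kind == "mask") a <- array(ifelse(a, 255L, 0L), dim(a))
  d <- dim(a)
  chunkShape <- as.integer(rep_len(chunkShape, 3L))
  attrs <- c(.sidecarAttrs(x, kind),
             list(format = "synconnect_chunked_v1", dtype = dtype,
                  shape = as.integer(d), chunk_shape = chunkShape))
  jsonlite::write_json(attrs, file.path(path, .ATTR_FILE), auto_unbox = TRUE,
                       digits = NA)
  rz <- .chunkRanges(d[1], chunkShape[1])
  ry <- .chunkRanges(d[2], chunkShape[2])
  rx <- .chunkRanges(d[3], chunkShape[3])
  for (ix in seq_along(rx)) for (iy in seq_along(ry)) for (iz in seq_along(rz)) {
    box <- c(rz[[iz]], ry[[iy]], rx[[ix]])
    part <- .sliceBox(a, box)
    f <- file.path(path, "chunks",
                   sprintf("%d_%d_%d.bin", iz - 1L, iy - 1L, ix - 1L))
    con <- file(f, "wb")
    switch(dtype,
      uint8 = writeBin(as.integer(part), con, size = 1L, endian = "little"),
      int32 = writeBin(as.integer(part), con, size = 4L, endian = "little"),
      float64 = writeBin(as.numeric(part), con, size = 8L, endian = "little"))
    close(con)
  }
  invisible(NULL)
}

.readChunkedStore <- function(path, voxelSize) {
  af <- file.path(path, .ATTR_FILE)
  if (!file.exists(af))
    stop("not a chunked store (missing ", .ATTR_FILE, "): ", path,
         call. = FALSE)
  attrs <- jsonlite::read_json(af)
  d <- as.integer(unlist(attrs$shape))
  chunkShape <- as.integer(unlist(attrs$chunk_shape))
  dtype <- attrs$dtype
  if (!dtype %in% c("uint8", "int32", "float64"))
    stop("unknown dtype in chunked store: ", dtype, call. = FALSE)
  kind <- if (!is.null(attrs$kind)) attrs$kind else "intensity"
  a <- array(if (dtype == "float64") 0 else 0L, d)
  rz <- .chunkRanges(d[1], chunkShape[1])
  ry <- .chunkRanges(d[2], chunkShape[2])
  rx <- .chunkRanges(d[3], chunkShape[3])
  for (ix in seq_along(rx)) for (iy in seq_along(ry)) for (iz in seq_along(rz)) {
    box <- c(rz[[iz]], ry[[iy]], rx[[ix]])
    nvox <- prod(box[c(2, 4, 6)] - box[c(1, 3, 5)] + 1L)
    f <- file.path(path, "chunks",
                   sprintf("%d_%d_%d.bin", iz - 1L, iy - 1L, ix - 1L))
    con <- file(f, "rb")
    part <- switch(dtype,
      uint8 = readBin(con, "integer", n = nvox, size = 1L, signed = FALSE,
                      endian = "little"),
      int32 = readBin(con, "integer", n = nvox, size = 4L, endian = "little"),
      float64 = readBin(con, "numeric", n = nvox, size = 8L,
                        endian = "little"))
    close(con)
    a[(box[1] + 1L):(box[2] + 1L), (box[3] + 1L):(box[4] + 1L),
      (box[5] + 1L):(box[6] + 1L)] <- part
  }
  vs <- .voxelSizeFromAttrs(attrs, voxelSize)
  org <- if (!is.null(attrs$origin_voxel))
    as.integer(unlist(attrs$origin_voxel)) else c(0L, 0L, 0L)
  .wrapVolume(a, kind, vs, org)
}

# ---- public entry points ----------------------------------------------------

#' Read a 3D volume
#'
#' Reads a TIFF slice series (`slice_00000.tif`, ...) or a chunked
#' N5-like store written by [writeVolume()].  Voxel-size metadata is taken
#' from the store's JSON attributes when present (the canonical
#' `voxel_size_nm` key is z,y,x; a foreign x,y,z-ordered `pixelResolution`
#' attribute is detected by key name and reversed), else from `voxelSize`.
#'
#' @param path directory of the series/store.
#' @param format `"auto"` (default), `"tiff_series"` or `"chunked_store"`.
#' @param voxelSize fallback voxel size (nm, z,y,x) when the store carries
#'   no metadata.
#' @return a [VoxelVolume-class], [BinaryMask-class] or [LabelVolume-class]
#'   according to the stored kind.
#' @export
readVolume <- function(path, format = c("auto", "tiff_series", "chunked_store"),
                       voxelSize = c(1, 1, 1)) {
  format <- match.arg(format)
  if (!dir.exists(path))
    stop("volume path does not exist: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(file.path(path, "chunks"))) "chunked_store"
              else "tiff_series"
  }
  switch(format,
    tiff_series = .readTiffSeries(path, voxelSize),
    chunked_store = .readChunkedStore(path, voxelSize))
}

#' Write a 3D volume
#'
#' Persists a volume as a TIFF slice series or a chunked store;
#' `readVolume(writeVolume(v))` reproduces the data exactly.  Binary masks
#' serialize as uint8 \{0, 255\} (common viewer convention); any nonzero
#' value reads back as foreground.
#'
#' @param x a [VoxelVolume-class], [BinaryMask-class] or [LabelVolume-class].
#' @param path output directory (created if needed).
#' @param format `"tiff_series"` or `"chunked_store"`.
#' @param chunkShape chunk edge lengths for the chunked store (default
#'   128^3, which divides the 512^3 analysis blocks evenly).
#' @return invisibly `NULL`.
#' @export
writeVolume <- function(x, path, format = c("tiff_series", "chunked_store"),
                        chunkShape = c(128L, 128L, 128L)) {
  format <- match.arg(format)
  stopifnot(is(x, "VoxelVolume"))
  switch(format,
    tiff_series = .writeTiffSeries(x, path),
    chunked_store = .writeChunkedStore(x, path, chunkShape))
  invisible(NULL)
}

# ---- CSV reports ------------------------------------------------------------

.SITE_COLS <- c("id", "stage", "voxel_count", "centroid_z", "centroid_y",
                "centroid_x", "bbox_zmin", "bbox_zmax", "bbox_ymin",
                "bbox_ymax", "bbox_xmin", "bbox_xmax", "extent_z", "extent_y",
                "extent_x", "assigned_mask_id")
.CONN_COLS <- c("pre_site_id", "post_object_id", "post_object_type",
                "overlap_voxels", "overlap_fraction", "contact_centroid_z",
                "contact_centroid_y", "contact_centroid_x")

.fmtNum <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Write a stage CSV report
#'
#' Writes synaptic-site or connection records as the fixed-column CSV the
#' pipeline emits per stage.  Centroids are printed with 3 decimals and
#' fractions with 6, in a fixed column order, so outputs are diffable.
#'
#' @param records data frame of site records (as produced by
#'   [detectSites()]/[runWorkflow()]) or connection records; an empty data
#'   frame yields a header-only CSV.
#' @param path output file.
#' @param stage stage tag recorded in each site row.
#' @return invisibly the formatted data frame that was written.
#' @export
writeSiteReport <- function(records, path, stage = "") {
  isConn <- "pre_site_id" %in% names(records)
  cols <- if (isConn) .CONN_COLS else .SITE_COLS
  out <- records
  if (!isConn) out$stage <- if (nrow(out)) stage else character(0)
  for (nm in setdiff(cols, names(out)))
    out[[nm]] <- rep(NA, nrow(out))
  out <- out[, cols, drop = FALSE]
  cent <- grep("centroid", cols, value = TRUE)
  for (nm in cent) out[[nm]] <- .fmtNum(as.numeric(out[[nm]]), 3L)
  if (isConn)
    out$overlap_fraction <- .fmtNum(as.numeric(out$overlap_fraction), 6L)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(out)
}
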