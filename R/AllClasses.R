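#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib SynConnect, .registration = TRUE
NULL

#' 3D intensity volume with voxel-size metadata
#'
#' A `VoxelVolume` is a 3D scalar grid in z,y,x axis order (dimension 1 is z)
#' with a per-axis voxel size in nanometres and the 0-based position of the
#' volume within a parent grid.  Probability volumes hold values in
#' \eqn{[0,1]}; integer volumes declare their bit depth through
#' `bitsPerSample`.
#'
#' @slot .Data numeric, integer or logical 3D array, axis order z,y,x.
#' @slot voxelSize numeric(3), voxel size in nm along z,y,x; all positive.
#' @slot origin integer(3), 0-based z,y,x offset of this (sub)volume inside
#'   its parent grid.
#'
#' @export
setClass("VoxelVolume",
  contains = "array",
  slots = c(voxelSize = "numeric", origin = "integer"),
  prototype = prototype(array(0, c(1, 1, 1)),
                        voxelSize = c(1, 1, 1), origin = c(0L, 0L, 0L)))

setValidity("VoxelVolume", function(object) {
  d <- dim(object@.Data)
  if (length(d) != 3L) return("data must be a 3D array (z,y,x)")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three positive finite values (z,y,x nm)")
  if (length(object@origin) != 3L || any(is.na(object@origin)) ||
      any(object@origin < 0L))
    return("origin must be three non-negative integers (0-based z,y,x)")
  TRUE
})

#' Binary foreground mask
#'
#' A [VoxelVolume] whose data are logical; `TRUE` marks foreground.
#'
#' @export
setClass("BinaryMask", contains = "VoxelVolume",
  prototype = prototype(array(FALSE, c(1, 1, 1)),
                        voxelSize = c(1, 1, 1), origin = c(0L, 0L, 0L)))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@.Data)) return("mask data must be logical")
  if (anyNA(object@.Data)) return("mask data must not contain NA")
  TRUE
})

#' Instance label volume
#'
#' A [VoxelVolume] of non-negative integer instance identifiers; 0 is
#' background.  After any relabeling operation labels are contiguous
#' \code{1..K}.
#'
#' @export
setClass("LabelVolume", contains = "VoxelVolume",
  prototype = prototype(array(0L, c(1, 1, 1)),
                        voxelSize = c(1, 1, 1), origin = c(0L, 0L, 0L)))

setValidity("LabelVolume", function(object) {
  if (!is.integer(object@.Data)) return("label data must be integer")
  if (anyNA(object@.Data)) return("label data must not contain NA")
  if (length(object@.Data) && min(object@.Data) < 0L)
    return("labels must be non-negative (0 = background)")
  TRUE
})

#' Threshold specification
#'
#' How to compute a global intensity threshold: Otsu (maximal between-class
#' variance), Li (iterative minimum cross-entropy) or a manual value.  The
#' thresholding rule everywhere in this package is `foreground = value >=
#' threshold`.
#'
#' @slot method one of `"otsu"`, `"li"`, `"manual"`.
#' @slot value manual threshold; must be set iff `method == "manual"`.
#' @export
setClass("ThresholdSpec",
  slots = c(method = "character", value = "numeric"),
  prototype = prototype(method = "otsu", value = NA_real_))

setValidity("ThresholdSpec", function(object) {
  if (!object@method %in% c("otsu", "li", "manual"))
    return("method must be one of 'otsu', 'li', 'manual'")
  if (object@method == "manual" && is.na(object@value))
    return("manual thresholding requires a value")
  if (object@method != "manual" && !is.na(object@value))
    return("value may only be set with method = 'manual'")
  TRUE
})

#' Gap-bridging parameters
#'
#' Parameters of the iterative 3D component-connecting step used on neuron
#' masks: gaps of at most `maxGap` voxels (Euclidean, voxel units) between
#' distinct components are closed by rasterizing the straight line between
#' the closest voxel pair, dilated by `bridgeRadius`; the process repeats
#' for `iterations` rounds or until stable.  The defaults (20 voxels, 4
#' iterations) are the values used throughout the connectivity analyses this
#' package reproduces.
#'
#' @export
setClass("BridgeSpec",
  slots = c(maxGap = "numeric", iterations = "integer",
            bridgeRadius = "integer"),
  prototype = prototype(maxGap = 20, iterations = 4L, bridgeRadius = 1L))

setValidity("BridgeSpec", function(object) {
  if (!is.finite(object@maxGap) || object@maxGap <= 0)
    return("maxGap must be a positive number of voxels")
  if (is.na(object@iterations) || object@iterations < 1L)
    return("iterations must be a positive integer")
  if (is.na(object@bridgeRadius) || object@bridgeRadius < 0L)
    return("bridgeRadius must be a non-negative integer")
  TRUE
})

#' Synaptic-site segmentation profile
#'
#' Per-marker-role parameters of punctate instance segmentation: probability
#' threshold (default 0.8), minimum instance size in voxels (presynaptic
#' default 400; postsynaptic and gap-junction default 200, both
#' inclusive-keep), and the minimum seed separation of the watershed split.
#'
#' @export
setClass("SegmentationProfile",
  slots = c(role = "character", probThreshold = "numeric",
            minSizeVoxels = "integer", minSeedSeparation = "integer"),
  prototype = prototype(role = "presynaptic", probThreshold = 0.8,
                        minSizeVoxels = 400L, minSeedSeparation = 3L))

setValidity("SegmentationProfile", function(object) {
  if (!object@role %in% c("presynaptic", "postsynaptic", "gap_junction"))
    return("role must be presynaptic, postsynaptic or gap_junction")
  if (!is.finite(object@probThreshold) || object@probThreshold <= 0 ||
      object@probThreshold >= 1)
    return("probThreshold must lie in (0, 1)")
  if (is.na(object@minSizeVoxels) || object@minSizeVoxels < 1L)
    return("minSizeVoxels must be a positive integer")
  if (is.na(object@minSeedSeparation) || object@minSeedSeparation < 1L)
    return("minSeedSeparation must be a positive integer")
  TRUE
})

#' Pipeline configuration
#'
#' One validated record holding every threshold the connectivity pipeline
#' uses.  The defaults are the published operating point: assignment
#' colocalization 0.5 ("50% or more" of the site volume inside the neuron
#' mask), contact colocalization 0.001 (0.1%, essentially any contact),
#' presynaptic size gate 400 voxels, postsynaptic/gap-junction gate 200,
#' neuron-component gate 2000, gap bridging at 20 voxels for 4 iterations,
#' probability threshold 0.8, and 512-voxel processing blocks.
#'
#' @export
setClass("PipelineConfig",
  slots = c(assignmentFraction = "numeric",
            contactFraction = "numeric",
            contactDilation = "integer",
            presynProfile = "SegmentationProfile",
            postsynProfile = "SegmentationProfile",
            gapJunctionProfile = "SegmentationProfile",
            maskThreshold = "ThresholdSpec",
            bridge = "BridgeSpec",
            maskMinSize = "integer",
            blockEdge = "integer",
            halo = "integer",
            connectivity = "integer",
            anisotropicDistance = "logical",
            seed = "integer"),
  prototype = prototype(assignmentFraction = 0.5,
                        contactFraction = 0.001,
                        contactDilation = 0L,
                        maskMinSize = 2000L,
                        blockEdge = 512L,
                        halo = 64L,
                        connectivity = 26L,
                        anisotropicDistance = FALSE,
                        seed = NA_integer_))

setValidity("PipelineConfig", function(object) {
  if (!is.finite(object@assignmentFraction) ||
      object@assignmentFraction < 0 || object@assignmentFraction > 1)
    return("assignmentFraction must lie in [0, 1]")
  if (!is.finite(object@contactFraction) ||
      object@contactFraction < 0 || object@contactFraction > 1)
    return("contactFraction must lie in [0, 1]")
  if (is.na(object@contactDilation) || object@contactDilation < 0L)
    return("contactDilation must be a non-negative integer")
  if (is.na(object@maskMinSize) || object@maskMinSize < 1L)
    return("maskMinSize must be a positive integer")
  if (is.na(object@blockEdge) || object@blockEdge < 1L)
    return("blockEdge must be a positive integer")
  if (is.na(object@halo) || object@halo < 0L)
    return("halo must be a non-negative integer")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  TRUE
})

#' Block decomposition of a volume
#'
#' Ceil-division tiling of a volume into cubic processing blocks with halos:
#' core boxes tile the volume exactly (edge blocks are smaller); each padded
#' box is the core grown by `halo` voxels, clipped at the volume boundary.
#' Boxes are 0-based inclusive `(zmin, zmax, ymin, ymax, xmin, xmax)` rows
#' of the `blocks` data frame, in z-fastest enumeration order.
#'
#' @export
setClass("BlockGrid",
  slots = c(volumeShape = "integer", blockEdge = "integer", halo = "integer",
            blocks = "data.frame"))

#' Workflow report
#'
#' Result container of the connectivity workflows: summary counts, per-stage
#' site tables, the connection table, and stage label volumes.
#'
#' @export
setClass("WorkflowReport",
  slots = c(kind = "integer", summary = "list", sites = "list",
            connections = "data.frame", labels = "list",
            config = "PipelineConfig"))

#' Detection evaluation metrics
#'
#' Instance-level confusion counts and precision/recall from one-to-one
#' matching of predicted against ground-truth instances, plus the per-pair
#' match table (pred id, gt id, overlap voxels, IoU).
#'
#' @export
setClass("DetectionMetrics",
  slots = c(truePositives = "integer", falsePositives = "integer",
            falseNegatives = "integer", precision = "numeric",
            recall = "numeric", matches = "data.frame", dice = "numeric"))

#' Phantom specification
#'
#' Parameters of the synthetic ground-truth generator; see
#' [phantomSpec()] for the meaning and defaults of each slot.
#'
#' @export
setClass("PhantomSpec",
  slots = c(volumeShape = "integer", nNeurons = "integer",
            tubeRadius = "numeric", tubeSteps = "integer",
            stepLength = "numeric", gapCount = "integer",
            gapLength = "integer", nPresynPerNeuron = "integer",
            presynSizeRange = "integer", nPostsynApposed = "integer",
            postsynSizeRange = "integer", apposedOverlapRange = "integer",
            nNoisePuncta = "integer", noiseSizeRange = "integer",
            backgroundSigma = "numeric", intensityLevels = "numeric",
            appositionMode = "character", seed = "integer"))

#' Phantom dataset with ground truth
#'
#' Synthetic channels plus the ground truth recorded during placement:
#' per-neuron masks as a [LabelVolume], per-channel site labels, the
#' site-to-neuron assignment table and the presynaptic/postsynaptic
#' connection table.
#'
#' @export
setClass("PhantomDataset",
  slots = c(neuronChannel = "VoxelVolume", presynChannel = "VoxelVolume",
            postsynChannel = "VoxelVolume", gtNeurons = "LabelVolume",
            gtPresyn = "LabelVolume", gtPostsyn = "LabelVolume",
            assignments = "data.frame", connections = "data.frame",
            spec = "PhantomSpec"))
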