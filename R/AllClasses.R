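#' @useDynLib phenocyte, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Parametric recipe for one phantom cell class
#'
#' Describes the morphology and staining intensity of a synthetic cell class
#' used by the phantom generator: nucleus and cytoplasm radii (mean and sd, in
#' pixels), actin texture spatial scale, mean foreground intensity per channel
#' on the raw camera scale, and nuclear eccentricity.
#'
#' @slot className single class name.
#' @slot nucleusRadius numeric length 2, mean and sd of the nucleus radius (px).
#' @slot cytoplasmRadius numeric length 2, mean and sd of the cytoplasm radius
#'   (px); the mean must exceed the nucleus mean.
#' @slot actinTextureScale positive spatial scale (px) of the actin speckle
#'   texture (Gaussian smoothing sigma of the texture field).
#' @slot channelIntensityMeans numeric length 4 mean foreground intensities for
#'   (brightfield, nuclear, actin, cytoplasm) on the raw camera scale.
#' @slot eccentricity nuclear eccentricity in [0, 1).
#' @exportClass PhantomClassParams
setClass("PhantomClassParams",
  representation(
    className = "character",
    nucleusRadius = "numeric",
    cytoplasmRadius = "numeric",
    actinTextureScale = "numeric",
    channelIntensityMeans = "numeric",
    eccentricity = "numeric"
  )
)

setValidity("PhantomClassParams", function(object) {
  msg <- character()
  if (length(object@className) != 1L || !nzchar(object@className))
    msg <- c(msg, "className must be a single non-empty string")
  for (s in c("nucleusRadius", "cytoplasmRadius")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] <= 0 || v[2] < 0)
      msg <- c(msg, sprintf("%s must be c(mean > 0, sd >= 0)", s))
  }
  if (length(object@cytoplasmRadius) == 2L && length(object@nucleusRadius) == 2L &&
      object@cytoplasmRadius[1] <= object@nucleusRadius[1])
    msg <- c(msg, "cytoplasm mean radius must exceed nucleus mean radius")
  if (length(object@actinTextureScale) != 1L || object@actinTextureScale <= 0)
    msg <- c(msg, "actinTextureScale must be a positive scalar")
  if (length(object@channelIntensityMeans) != 4L ||
      any(object@channelIntensityMeans < 0))
    msg <- c(msg, "channelIntensityMeans must be 4 non-negative values")
  if (length(object@eccentricity) != 1L ||
      object@eccentricity < 0 || object@eccentricity >= 1)
    msg <- c(msg, "eccentricity must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' One imaging field: four co-registered intensity rasters
#'
#' @slot planes numeric array of dim (H, W, 4), channel order
#'   (brightfield, nuclear, actin, cytoplasm).
#' @slot bitDepth camera bit depth; intensities must lie in
#'   [0, 2^bitDepth - 1].
#' @slot fieldId single field identifier.
#' @exportClass WidefieldFrame
setClass("WidefieldFrame",
  representation(planes = "array", bitDepth = "integer", fieldId = "character")
)

setValidity("WidefieldFrame", function(object) {
  d <- dim(object@planes)
  msg <- character()
  if (length(d) != 3L || d[3] != 4L)
    msg <- c(msg, "planes must be an (H, W, 4) array")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
    msg <- c(msg, "bitDepth must be a positive integer")
  else {
    r <- range(object@planes)
    if (!all(is.finite(r)) || r[1] < 0 || r[2] > 2^object@bitDepth - 1)
      msg <- c(msg, "intensities must be finite and within [0, 2^bitDepth - 1]")
  }
  if (length(object@fieldId) != 1L)
    msg <- c(msg, "fieldId must be a single string")
  if (length(msg)) msg else TRUE
})

#' A synthetic scene: frame plus ground truth
#'
#' @slot frame a [WidefieldFrame-class].
#' @slot truth data.frame with columns row, col, kind
#'   (viable_cell, doublet, dead_cell, debris, border_cell) and class
#'   (class name for viable cells, NA otherwise).
#' @exportClass PhantomScene
setClass("PhantomScene",
  representation(frame = "WidefieldFrame", truth = "data.frame")
)

.scene_kinds <- c("viable_cell", "doublet", "dead_cell", "debris", "border_cell")

setValidity("PhantomScene", function(object) {
  msg <- character()
  tr <- object@truth
  need <- c("row", "col", "kind", "class")
  if (!all(need %in% names(tr)))
    return("truth must have columns row, col, kind, class")
  if (nrow(tr)) {
    d <- dim(object@frame@planes)
    if (any(tr$row < 1 | tr$row > d[1] | tr$col < 1 | tr$col > d[2]))
      msg <- c(msg, "every truth centroid must lie inside the frame")
    if (!all(tr$kind %in% .scene_kinds))
      msg <- c(msg, "unknown object kind in truth")
    if (any(tr$kind == "viable_cell" & is.na(tr$class)))
      msg <- c(msg, "viable_cell records must carry a class name")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled collection of normalized single-cell patches
#'
#' Pixel values are normalized to [0, 1]; spatial shape is fixed (75 x 75 by
#' default) with channels in the order (brightfield, nuclear, actin,
#' cytoplasm) unless a single-channel subset was taken.
#'
#' @slot pixels numeric array of dim (H, W, C, N).
#' @slot labels character vector of length N (NA allowed for unlabeled).
#' @slot centroids N x 2 matrix of (row, col) frame coordinates.
#' @slot fieldIds character vector of length N.
#' @slot channelNames character vector of length C.
#' @slot normMode normalization rule tag ("bitdepth" or "minmax").
#' @exportClass PatchSet
setClass("PatchSet",
  representation(
    pixels = "array", labels = "character", centroids = "matrix",
    fieldIds = "character", channelNames = "character", normMode = "character"
  )
)

setValidity("PatchSet", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 4L)
    return("pixels must be an (H, W, C, N) array")
  n <- d[4]
  if (length(object@labels) != n) msg <- c(msg, "labels length must equal N")
  if (!is.matrix(object@centroids) || nrow(object@centroids) != n ||
      ncol(object@centroids) != 2L)
    msg <- c(msg, "centroids must be an N x 2 matrix")
  if (length(object@fieldIds) != n) msg <- c(msg, "fieldIds length must equal N")
  if (length(object@channelNames) != d[3])
    msg <- c(msg, "channelNames length must equal C")
  if (n > 0) {
    r <- range(object@pixels)
    if (!all(is.finite(r)) || r[1] < 0 || r[2] > 1)
      msg <- c(msg, "pixel values must be finite and within [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Architecture descriptor for the patch classifier
#'
#' The reference architecture: four convolution blocks of widths
#' (256, 128, 64, 64) with kernels (7, 5, 3, 3) and stride 1, each followed by
#' batch normalization and ReLU, with 2 x 2 max-pooling after blocks 1, 2 and
#' 4; then three 128-node fully connected blocks (batch norm, ReLU, 20%
#' dropout) and a softmax output.  `widthScale` shrinks every width for
#' desk-scale work; `poolStride` may be 2 (conventional) or 1 (literal
#' near-full-size pooling).
#'
#' @slot inputChannels 1 or 4.
#' @slot inputSize spatial input size (75).
#' @slot nClasses number of output classes (>= 2).
#' @slot convWidths,kernelSizes integer length 4.
#' @slot fcWidths integer length 3.
#' @slot poolSize,poolStride pooling window and stride.
#' @slot dropoutRate dropout fraction in [0, 1).
#' @slot padding "valid" or "same".
#' @slot widthScale multiplicative width scale in (0, 1].
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(
    inputChannels = "integer", inputSize = "integer", nClasses = "integer",
    convWidths = "integer", kernelSizes = "integer", fcWidths = "integer",
    poolSize = "integer", poolStride = "integer", dropoutRate = "numeric",
    padding = "character", widthScale = "numeric"
  )
)

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (!object@inputChannels %in% c(1L, 4L))
    msg <- c(msg, "inputChannels must be 1 or 4")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (length(object@convWidths) != 4L || length(object@kernelSizes) != 4L)
    msg <- c(msg, "convWidths and kernelSizes must have length 4")
  if (length(object@fcWidths) != 3L) msg <- c(msg, "fcWidths must have length 3")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (!object@padding %in% c("valid", "same"))
    msg <- c(msg, "padding must be 'valid' or 'same'")
  if (!object@poolStride %in% c(1L, 2L))
    msg <- c(msg, "poolStride must be 1 or 2")
  if (object@widthScale <= 0 || object@widthScale > 1)
    msg <- c(msg, "widthScale must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' A (possibly trained) patch classifier
#'
#' Holds the architecture descriptor, the layer parameter store, per-epoch
#' training history, the set of frozen layer ids (transfer learning) and the
#' ordered class names.
#'
#' @slot spec a [NetworkSpec-class].
#' @slot layers list of layer parameter records (internal layout).
#' @slot history data.frame with one row per trained epoch.
#' @slot classNames ordered class names; length equals `nClasses`.
#' @slot frozenLayers integer ids of frozen layers.
#' @slot frozenDigest md5 digest of the frozen parameters ("" if none).
#' @slot seed integer seed used to initialize the parameters.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(
    spec = "NetworkSpec", layers = "list", history = "data.frame",
    classNames = "character", frozenLayers = "integer",
    frozenDigest = "character", seed = "integer"
  )
)

setValidity("TrainedModel", function(object) {
  if (length(object@classNames) != object@spec@nClasses)
    return("classNames length must equal nClasses")
  TRUE
})

#' Stratified k-fold assignment of a dataset
#'
#' @slot k number of folds.
#' @slot assignments integer fold index (1..k) per item.
#' @slot seed seed used for the partition.
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(k = "integer", assignments = "integer", seed = "integer")
)

setValidity("FoldPlan", function(object) {
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > object@k))
    return("assignments must lie in 1..k")
  TRUE
})
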