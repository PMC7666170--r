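#' @include AllClasses.R
NULL

#' Number of patches in a PatchSet
#' @param x a [PatchSet-class].
#' @return integer count.
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @describeIn nPatches patch count
setMethod("nPatches", "PatchSet", function(x) dim(x@pixels)[4])

#' Patch labels
#' @param x a [PatchSet-class].
#' @return character vector of class labels (NA where unlabeled).
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))

#' @describeIn patchLabels class labels
setMethod("patchLabels", "PatchSet", function(x) x@labels)

#' Replace patch labels
#' @param x a [PatchSet-class].
#' @param value character vector of length `nPatches(x)`.
#' @export
setGeneric("patchLabels<-", function(x, value) standardGeneric("patchLabels<-"))

#' @describeIn patchLabels replace labels
setMethod("patchLabels<-", "PatchSet", function(x, value) {
  x@labels <- as.character(value)
  validObject(x)
  x
})

#' Patch pixel array
#' @param x a [PatchSet-class].
#' @return numeric array of dim (H, W, C, N).
#' @export
setGeneric("patchPixels", function(x) standardGeneric("patchPixels"))

#' @describeIn patchPixels pixel array
setMethod("patchPixels", "PatchSet", function(x) x@pixels)

#' Channel names of a PatchSet or frame
#' @param x a [PatchSet-class] or [WidefieldFrame-class].
#' @return character vector.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @describeIn channelNames channel names of the patch set
setMethod("channelNames", "PatchSet", function(x) x@channelNames)

#' @describeIn channelNames channel names of a frame (fixed order)
setMethod("channelNames", "WidefieldFrame", function(x)
  c("brightfield", "nuclear", "actin", "cytoplasm"))

#' Class names of a model
#' @param x a [TrainedModel-class].
#' @return ordered character vector of class names.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @describeIn classNames model class names
setMethod("classNames", "TrainedModel", function(x) x@classNames)

#' Architecture descriptor of a model
#' @param x a [TrainedModel-class].
#' @return the [NetworkSpec-class].
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))

#' @describeIn modelSpec network spec
setMethod("modelSpec", "TrainedModel", function(x) x@spec)

#' Per-epoch training history
#' @param x a [TrainedModel-class].
#' @return data.frame with one row per trained epoch.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @describeIn trainingHistory training history
setMethod("trainingHistory", "TrainedModel", function(x) x@history)

#' Fold assignments
#' @param x a [FoldPlan-class].
#' @return integer fold index per item.
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @describeIn foldAssignments fold index per item
setMethod("foldAssignments", "FoldPlan", function(x) x@assignments)

#' Ground truth table of a phantom scene
#' @param x a [PhantomScene-class].
#' @return data.frame with columns row, col, kind, class.
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @describeIn sceneTruth truth table
setMethod("sceneTruth", "PhantomScene", function(x) x@truth)

#' Frame of a phantom scene
#' @param x a [PhantomScene-class].
#' @return the [WidefieldFrame-class].
#' @export
setGeneric("sceneFrame", function(x) standardGeneric("sceneFrame"))

#' @describeIn sceneFrame frame
setMethod("sceneFrame", "PhantomScene", function(x) x@frame)

#' Frame planes accessor
#' @param x a [WidefieldFrame-class].
#' @return numeric (H, W, 4) array.
#' @export
setGeneric("framePlanes", function(x) standardGeneric("framePlanes"))

#' @describeIn framePlanes raw plane array
setMethod("framePlanes", "WidefieldFrame", function(x) x@planes)

#' @export
setMethod("show", "PatchSet", function(object) {
  d <- dim(object@pixels)
  labs <- object@labels[!is.na(object@labels)]
  cat(sprintf("PatchSet: %d patches of %dx%dx%d [%s]\n",
              d[4], d[1], d[2], d[3], object@normMode))
  if (length(labs)) {
    tab <- table(labs)
    cat("  classes:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  } else if (d[4] > 0) cat("  unlabeled\n")
  invisible(NULL)
})

#' @export
setMethod("show", "WidefieldFrame", function(object) {
  d <- dim(object@planes)
  cat(sprintf("WidefieldFrame '%s': %d x %d px, 4 channels, %d-bit\n",
              object@fieldId, d[1], d[2], object@bitDepth))
  invisible(NULL)
})

#' @export
setMethod("show", "PhantomScene", function(object) {
  show(object@frame)
  tab <- table(factor(object@truth$kind, levels = .scene_kinds))
  cat("  truth:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                        collapse = ", "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "TrainedModel", function(object) {
  s <- object@spec
  cat(sprintf("TrainedModel: %d-channel input, %d classes, width scale %g\n",
              s@inputChannels, s@nClasses, s@widthScale))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final accuracy %.3f\n",
                nrow(object@history),
                object@history$accuracy[nrow(object@history)]))
  else cat("  untrained\n")
  if (length(object@frozenLayers))
    cat("  frozen layers:", paste(object@frozenLayers, collapse = ","), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf(
    "NetworkSpec: %dx%dx%d input -> conv(%s; k=%s) -> fc(%s) -> %d classes\n",
    object@inputSize, object@inputSize, object@inputChannels,
    paste(scaledWidths(object)$conv, collapse = ","),
    paste(object@kernelSizes, collapse = ","),
    paste(scaledWidths(object)$fc, collapse = ","),
    object@nClasses))
  cat(sprintf("  padding %s, pool %dx%d stride %d, dropout %.2f\n",
              object@padding, object@poolSize, object@poolSize,
              object@poolStride, object@dropoutRate))
  invisible(NULL)
})

#' Subset a PatchSet
#' @param x a [PatchSet-class].
#' @param i index vector of patches to keep.
#' @param j,...,drop ignored.
#' @return a [PatchSet-class] with the selected patches.
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  new("PatchSet",
      pixels = x@pixels[, , , i, drop = FALSE],
      labels = x@labels[i],
      centroids = x@centroids[i, , drop = FALSE],
      fieldIds = x@fieldIds[i],
      channelNames = x@channelNames,
      normMode = x@normMode)
})
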