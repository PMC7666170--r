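#' @include AllClasses.R network.R
NULL

.conv_stage_param_layers <- function(model)
  which(vapply(model@layers, function(l)
    identical(l$stage, "conv") && length(.param_names(l)) > 0, TRUE))

.frozen_params <- function(model) {
  lapply(model@frozenLayers, function(i) {
    l <- model@layers[[i]]
    l[.param_names(l)]
  })
}

#' Freeze the convolution stage of a model
#'
#' Marks all convolution layers (and their batch normalizations, including
#' the running statistics) as non-trainable and records an md5 digest of the
#' frozen parameters so later training can be audited for bitwise
#' invariance.  Frozen batch normalizations run in inference mode during any
#' subsequent training.
#'
#' @param model a [TrainedModel-class]; freezing an untrained model is
#'   allowed but warned about.
#' @return the model with the convolution stage frozen.
#' @export
freezeConv <- function(model) {
  if (!nrow(model@history))
    warning("freezing an untrained model: the frozen features are random",
            call. = FALSE)
  model@frozenLayers <- .conv_stage_param_layers(model)
  model@frozenDigest <- .param_digest(.frozen_params(model))
  model
}

#' Digest of a model's frozen parameters
#' @param model a [TrainedModel-class] with frozen layers.
#' @return md5 string of the frozen parameter values.
#' @export
frozenDigest <- function(model) {
  if (!length(model@frozenLayers)) return("")
  .param_digest(.frozen_params(model))
}

#' Count trainable and frozen parameters
#' @param model a [TrainedModel-class].
#' @return named vector with `trainable` and `frozen` parameter counts.
#' @export
parameterCounts <- function(model) {
  cnt <- function(ids) sum(vapply(ids, function(i) {
    l <- model@layers[[i]]
    sum(vapply(.param_names(l), function(p) length(l[[p]]), 0))
  }, 0))
  param_ids <- which(vapply(model@layers,
                            function(l) length(.param_names(l)) > 0, TRUE))
  frozen <- intersect(param_ids, model@frozenLayers)
  c(trainable = cnt(setdiff(param_ids, frozen)), frozen = cnt(frozen))
}

#' Replace the classification head
#'
#' Re-initializes the output layer at a new width (one node per new class);
#' every other parameter is retained bitwise, so penultimate features are
#' unchanged.
#'
#' @param model a [TrainedModel-class].
#' @param newClassNames ordered names of the new classes (>= 2).
#' @param seed seed for the new head's initialization.
#' @return the model with a fresh `length(newClassNames)`-node output layer.
#' @export
replaceHead <- function(model, newClassNames, seed = 1L) {
  if (length(newClassNames) < 2L) .stopf("need at least 2 new classes")
  head_id <- max(which(vapply(model@layers, function(l)
    identical(l$type, "fc"), TRUE)))
  inF <- ncol(model@layers[[head_id]]$W)
  k <- length(newClassNames)
  .with_seed(seed, {
    model@layers[[head_id]]$W <- matrix(.he_unif(k * inF, inF), k, inF)
    model@layers[[head_id]]$b <- numeric(k)
  })
  model@spec@nClasses <- as.integer(k)
  model@classNames <- as.character(newClassNames)
  model@history <- data.frame()
  validObject(model)
  model
}

#' Transfer-train a model on a new class set
#'
#' Freezes the convolution stage of the base model, replaces the output head
#' for the new classes, and trains only the fully connected stage with the
#' same hyperparameter family as base training (Adam, lr 0.001, 25 epochs by
#' default).  The frozen-parameter digest is verified bitwise after
#' training.
#'
#' @param baseModel a trained [TrainedModel-class].
#' @param newDataset a labeled [PatchSet-class] of the new classes; patch
#'   shape and channels must match the base model input.
#' @param newClassNames ordered new class names; defaults to the sorted
#'   classes of `newDataset`.
#' @param epochs,lr,batchSize training hyperparameters.
#' @param seed seed.
#' @param valData optional validation [PatchSet-class].
#' @param verbose print per-epoch progress.
#' @return the transferred [TrainedModel-class] (frozen conv stage, new
#'   head, filled history).
#' @export
transferTrain <- function(baseModel, newDataset, newClassNames = NULL,
                          epochs = 25L, lr = 0.001, batchSize = 64L,
                          seed = 1L, valData = NULL, verbose = FALSE) {
  if (is.null(newClassNames))
    newClassNames <- sort(unique(patchLabels(newDataset)))
  model <- freezeConv(baseModel)
  model <- replaceHead(model, newClassNames, seed = seed)
  digest_before <- frozenDigest(model)
  model <- trainNetwork(model, newDataset, epochs = epochs, lr = lr,
                        batchSize = batchSize, seed = seed, valData = valData,
                        verbose = verbose)
  if (!identical(frozenDigest(model), digest_before))
    .stopf("frozen parameters changed during transfer training")
  model
}
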