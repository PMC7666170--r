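#' @include AllClasses.R utils.R
NULL

#' Rotate a patch by a multiple of 90 degrees
#'
#' Rotates all channels jointly by `(k mod 4) * 90` degrees counter-clockwise.
#' The rotation is a pixel permutation: lossless, and per-channel histograms
#' are preserved exactly.
#'
#' @param patch numeric (H, W, C) array (or (H, W) matrix).
#' @param k any integer number of quarter turns.
#' @return the rotated patch.
#' @export
augmentRotate <- function(patch, k) {
  if (is.matrix(patch)) return(.rot90(patch, k))
  d <- dim(patch)
  if (length(d) != 3L) .stopf("patch must be (H, W, C) or a matrix")
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(patch)
  out <- array(0, if (k %% 2 == 0) d else c(d[2], d[1], d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- .rot90(patch[, , ch], k)
  out
}

#' Plan a class-balancing operation (bookkeeping only)
#'
#' Computes, per class, which items to keep and which rotation-augmented
#' copies to add so that every class ends at exactly `targetPerClass` items:
#' classes above target are uniformly subsampled without replacement;
#' classes below target are padded with rotated copies (rotation k drawn from
#' {1, 2, 3} so a copy is never pixel-identical to its source); classes at
#' target pass through.
#'
#' @param counts named integer vector of per-class item counts.
#' @param targetPerClass target count per class.
#' @param seed sampling seed.
#' @return data.frame with columns class, source (item index within the
#'   class), rotation (0 for originals); exactly
#'   `targetPerClass * length(counts)` rows.
#' @export
balancePlan <- function(counts, targetPerClass, seed = 1L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    .stopf("counts must be a named vector")
  empty <- names(counts)[counts < 1]
  if (length(empty))
    .stopf("empty class(es): %s", paste(empty, collapse = ", "))
  .with_seed(seed, {
    rows <- lapply(names(counts), function(cl) {
      n <- counts[[cl]]
      if (n > targetPerClass) {
        data.frame(class = cl,
                   source = sort(sample.int(n, targetPerClass)),
                   rotation = 0L, stringsAsFactors = FALSE)
      } else if (n == targetPerClass) {
        data.frame(class = cl, source = seq_len(n), rotation = 0L,
                   stringsAsFactors = FALSE)
      } else {
        deficit <- targetPerClass - n
        data.frame(class = cl,
                   source = c(seq_len(n),
                              sample.int(n, deficit, replace = TRUE)),
                   rotation = c(rep(0L, n),
                                sample(1:3, deficit, replace = TRUE)),
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  })
}

#' Balance a patch dataset by subsampling and rotation augmentation
#'
#' Applies a [balancePlan()] to the pixels: every class ends at exactly
#' `targetPerClass` patches.
#'
#' @param dataset a labeled [PatchSet-class].
#' @param targetPerClass target patches per class.
#' @param seed sampling seed.
#' @return a balanced [PatchSet-class] of
#'   `targetPerClass * nClasses` patches, grouped by class.
#' @export
balanceClasses <- function(dataset, targetPerClass, seed = 1L) {
  labels <- patchLabels(dataset)
  if (anyNA(labels)) .stopf("dataset contains unlabeled patches")
  counts <- table(labels)
  plan <- balancePlan(stats::setNames(as.integer(counts), names(counts)),
                      targetPerClass, seed)
  d <- dim(dataset@pixels)
  n_out <- nrow(plan)
  px <- array(0, c(d[1:3], n_out))
  ctrs <- matrix(NA_real_, n_out, 2, dimnames = list(NULL, c("row", "col")))
  fids <- character(n_out)
  class_idx <- split(seq_along(labels), labels)
  for (i in seq_len(n_out)) {
    j <- class_idx[[plan$class[i]]][plan$source[i]]
    patch <- dataset@pixels[, , , j]
    if (plan$rotation[i] != 0L) patch <- augmentRotate(patch, plan$rotation[i])
    px[, , , i] <- patch
    ctrs[i, ] <- dataset@centroids[j, ]
    fids[i] <- dataset@fieldIds[j]
  }
  new("PatchSet", pixels = px, labels = plan$class, centroids = ctrs,
      fieldIds = fids, channelNames = dataset@channelNames,
      normMode = dataset@normMode)
}

#' Seeded balanced subsample (e.g. a fixed-size test set per class)
#'
#' @param dataset a labeled [PatchSet-class].
#' @param nPerClass items per class to draw (without replacement).
#' @param seed sampling seed.
#' @return a [PatchSet-class] with `nPerClass` patches per class.
#' @export
balancedSubsample <- function(dataset, nPerClass, seed = 1L) {
  labels <- patchLabels(dataset)
  idx <- .with_seed(seed, {
    unlist(lapply(split(seq_along(labels), labels), function(ii) {
      if (length(ii) < nPerClass)
        .stopf("class has only %d items, need %d", length(ii), nPerClass)
      sample(ii, nPerClass)
    }), use.names = FALSE)
  })
  dataset[sort(idx)]
}
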