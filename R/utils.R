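#' @include AllClasses.R
NULL

# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a PatchSet
#'
#' @param pixels numeric (H, W, C, N) array with values in [0, 1].
#' @param labels optional character labels (length N).
#' @param centroids optional N x 2 matrix of frame coordinates.
#' @param fieldIds optional character field ids.
#' @param channelNames channel names (length C).
#' @param normMode normalization tag, "bitdepth" or "minmax".
#' @return a [PatchSet-class].
#' @export
PatchSet <- function(pixels, labels = NULL, centroids = NULL, fieldIds = NULL,
                     channelNames = c("brightfield", "nuclear", "actin",
                                      "cytoplasm"),
                     normMode = "bitdepth") {
  d <- dim(pixels)
  if (length(d) != 4L) .stopf("pixels must be an (H, W, C, N) array")
  n <- d[4]
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(centroids))
    centroids <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  if (is.null(fieldIds)) fieldIds <- rep(NA_character_, n)
  new("PatchSet", pixels = pixels, labels = as.character(labels),
      centroids = centroids, fieldIds = as.character(fieldIds),
      channelNames = channelNames[seq_len(d[3])], normMode = normMode)
}

#' Combine patch sets
#'
#' Refuses to merge sets whose channel layout or normalization mode differ,
#' since mixed normalizations silently corrupt training.
#'
#' @param ... [PatchSet-class] objects.
#' @return a single [PatchSet-class].
#' @export
combinePatchSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "PatchSet"))
    sets <- sets[[1]]
  if (!length(sets)) .stopf("no patch sets given")
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s@channelNames, ref@channelNames))
      .stopf("cannot merge: channel layout differs (%s vs %s)",
             paste(ref@channelNames, collapse = ","),
             paste(s@channelNames, collapse = ","))
    if (!identical(s@normMode, ref@normMode))
      .stopf("cannot merge: normalization mode differs ('%s' vs '%s')",
             ref@normMode, s@normMode)
    dr <- dim(ref@pixels)[1:3]; ds <- dim(s@pixels)[1:3]
    if (!identical(dr, ds)) .stopf("cannot merge: patch shapes differ")
  }
  d <- dim(ref@pixels)[1:3]
  n <- sum(vapply(sets, nPatches, integer(1)))
  px <- array(0, c(d, n))
  at <- 0L
  for (s in sets) {
    k <- nPatches(s)
    if (k) px[, , , at + seq_len(k)] <- s@pixels
    at <- at + k
  }
  new("PatchSet", pixels = px,
      labels = unlist(lapply(sets, slot, "labels"), use.names = FALSE),
      centroids = do.call(rbind, lapply(sets, slot, "centroids")),
      fieldIds = unlist(lapply(sets, slot, "fieldIds"), use.names = FALSE),
      channelNames = ref@channelNames, normMode = ref@normMode)
}

#' Restrict a PatchSet to a channel subset
#'
#' Used to train single-channel model variants: the spatial content is
#' untouched, only the channel axis is subset.
#'
#' @param x a [PatchSet-class].
#' @param channels channel names or indices to keep.
#' @return a [PatchSet-class] with the selected channels.
#' @export
channelSubset <- function(x, channels) {
  idx <- if (is.character(channels)) match(channels, x@channelNames)
         else as.integer(channels)
  if (anyNA(idx)) .stopf("unknown channel(s): %s",
                         paste(channels[is.na(idx)], collapse = ", "))
  new("PatchSet", pixels = x@pixels[, , idx, , drop = FALSE],
      labels = x@labels, centroids = x@centroids, fieldIds = x@fieldIds,
      channelNames = x@channelNames[idx], normMode = x@normMode)
}

# md5 digest of an arbitrary R object (serialized deterministically)
.param_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

# rotate one (H, W) matrix 90 degrees counter-clockwise k times:
# new[i, j] = m[j, W - i + 1]
.rot90 <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) {
    tm <- t(m)
    m <- tm[rev(seq_len(nrow(tm))), , drop = FALSE]
  }
  m
}
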