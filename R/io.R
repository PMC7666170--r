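#' @include AllClasses.R utils.R
NULL

.channel_suffixes <- c(brightfield = "bf", nuclear = "nuc", actin = "actin",
                       cytoplasm = "cyto")

#' Write a scene (or frame) as per-channel TIFFs plus ground truth
#'
#' One 16-bit grayscale TIFF per channel, named
#' `<field>_<bf|nuc|actin|cyto>.tif`, and for scenes a `<field>_truth.tsv`
#' with columns row, col, kind, class.
#'
#' @param x a [PhantomScene-class] or [WidefieldFrame-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeScene <- function(x, dir) {
  frame <- if (is(x, "PhantomScene")) sceneFrame(x) else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in seq_len(4)) {
    p <- file.path(dir, sprintf("%s_%s.tif", frame@fieldId,
                                .channel_suffixes[ch]))
    tiff::writeTIFF(frame@planes[, , ch] / 65535, p, bits.per.sample = 16L,
                    compression = "deflate")
    paths <- c(paths, p)
  }
  if (is(x, "PhantomScene")) {
    p <- file.path(dir, sprintf("%s_truth.tsv", frame@fieldId))
    utils::write.table(sceneTruth(x), p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.read_channel_tiff <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e)
                    .stopf("unreadable TIFF '%s': %s", path,
                           conditionMessage(e)))
  if (length(dim(img)) == 3L) img <- img[, , 1]  # tolerate stored gray+alpha
  bits <- attr(img, "bits.per.sample")
  list(data = unclass(img), bits = if (is.null(bits)) NA_integer_ else bits)
}

#' Read widefield frames from per-channel TIFF files
#'
#' Channel files are located either by the filename suffix convention
#' `<field>_<bf|nuc|actin|cyto>.tif` inside a directory, or through an
#' explicit manifest TSV with columns field, channel
#' (brightfield/nuclear/actin/cytoplasm or bf/nuc/actin/cyto) and path.  All
#' four channels of a field must be present with identical shapes and stored
#' bit depths.
#'
#' @param dir directory to scan (suffix convention).
#' @param manifest path to a manifest TSV (overrides `dir`).
#' @param bitDepth acquisition bit depth of the intensities (the TIFF
#'   container is 16-bit; cameras commonly fill 14 bits of it).
#' @param tolerant if TRUE, fields with errors are skipped with a warning
#'   instead of failing the whole read.
#' @return named list of [WidefieldFrame-class] objects.
#' @export
readWidefieldTiffs <- function(dir = NULL, manifest = NULL, bitDepth = 14L,
                               tolerant = FALSE) {
  if (is.null(dir) && is.null(manifest))
    .stopf("give either dir or manifest")
  if (!is.null(manifest)) {
    mf <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    need <- c("field", "channel", "path")
    if (!all(need %in% names(mf)))
      .stopf("manifest must have columns field, channel, path")
    mf$channel <- ifelse(mf$channel %in% names(.channel_suffixes),
                         .channel_suffixes[mf$channel], mf$channel)
  } else {
    files <- list.files(dir, pattern = "_(bf|nuc|actin|cyto)\\.tif{1,2}$",
                        full.names = TRUE)
    if (!length(files)) .stopf("no channel TIFFs found in '%s'", dir)
    base <- sub("\\.tif{1,2}$", "", basename(files))
    mf <- data.frame(field = sub("_(bf|nuc|actin|cyto)$", "", base),
                     channel = sub("^.*_(bf|nuc|actin|cyto)$", "\\1", base),
                     path = files, stringsAsFactors = FALSE)
  }
  frames <- list()
  for (fid in unique(mf$field)) {
    res <- tryCatch({
      sel <- mf[mf$field == fid, ]
      missing <- setdiff(unname(.channel_suffixes), sel$channel)
      if (length(missing))
        .stopf("field '%s': missing channel file(s): %s", fid,
               paste(missing, collapse = ", "))
      chans <- lapply(unname(.channel_suffixes), function(sfx)
        .read_channel_tiff(sel$path[match(sfx, sel$channel)]))
      shapes <- vapply(chans, function(x) dim(x$data), integer(2))
      if (any(shapes != shapes[, 1]))
        .stopf("field '%s': channel shapes differ", fid)
      bits <- vapply(chans, function(x) x$bits, 0L)
      if (length(unique(bits[!is.na(bits)])) > 1L)
        .stopf("field '%s': mixed stored bit depths (%s)", fid,
               paste(bits, collapse = ", "))
      planes <- array(0, c(shapes[1, 1], shapes[2, 1], 4))
      for (ch in 1:4) planes[, , ch] <- chans[[ch]]$data
      new("WidefieldFrame", planes = planes, bitDepth = as.integer(bitDepth),
          fieldId = fid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (tolerant) {
        warning(sprintf("skipping field '%s': %s", fid,
                        conditionMessage(res)), call. = FALSE)
        next
      }
      stop(res)
    }
    frames[[fid]] <- res
  }
  frames
}

# ---- patch archive ---------------------------------------------------------

.archive_digest <- function(channelNames, normMode, shape)
  .param_digest(list(channelNames, normMode, as.integer(shape)))

#' Write a patch archive
#'
#' Serializes a [PatchSet-class] losslessly to a directory containing
#' `manifest.json` (shape, channel order, normalization tag, content
#' digest), `labels.tsv` (label and provenance per patch) and `pixels.bin`
#' (little-endian float64 pixel block).  The round trip through
#' [readPatchArchive()] is bitwise exact.
#'
#' @param patches a nonempty [PatchSet-class].
#' @param path archive directory to create.
#' @param seed optional creation seed recorded in the manifest.
#' @return invisibly, `path`.
#' @export
writePatchArchive <- function(patches, path, seed = NULL) {
  n <- nPatches(patches)
  if (!n) .stopf("refusing to write an empty patch archive")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(patches@pixels)
  manifest <- list(format = "phenocyte-patch-archive", version = 1L,
                   n = n, shape = d[1:3],
                   channelNames = patches@channelNames,
                   normMode = patches@normMode,
                   configDigest = .archive_digest(patches@channelNames,
                                                  patches@normMode, d[1:3]),
                   seed = seed)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(
    data.frame(label = patches@labels, field_id = patches@fieldIds,
               row = patches@centroids[, 1], col = patches@centroids[, 2],
               stringsAsFactors = FALSE),
    file.path(path, "labels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  con <- file(file.path(path, "pixels.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(patches@pixels), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a patch archive
#' @param path archive directory written by [writePatchArchive()].
#' @return the stored [PatchSet-class].
#' @export
readPatchArchive <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) .stopf("'%s' is not a patch archive", path)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(m$format, "phenocyte-patch-archive"))
    .stopf("'%s' is not a patch archive", path)
  lab <- utils::read.delim(file.path(path, "labels.tsv"),
                           stringsAsFactors = FALSE, na.strings = "NA")
  n <- m$n
  shape <- as.integer(m$shape)
  con <- file(file.path(path, "pixels.bin"), "rb")
  on.exit(close(con))
  px <- readBin(con, "numeric", n = prod(shape) * n, size = 8L,
                endian = "little")
  dim(px) <- c(shape, n)
  new("PatchSet", pixels = px, labels = as.character(lab$label),
      centroids = cbind(row = as.numeric(lab$row), col = as.numeric(lab$col)),
      fieldIds = as.character(lab$field_id),
      channelNames = as.character(m$channelNames),
      normMode = m$normMode)
}

#' Merge patch archives
#'
#' Refuses to merge archives whose configuration digests (channel order,
#' normalization mode, patch shape) differ.
#'
#' @param paths archive directories.
#' @param out output archive directory.
#' @return invisibly, `out`.
#' @export
mergePatchArchives <- function(paths, out) {
  mans <- lapply(paths, function(p)
    jsonlite::read_json(file.path(p, "manifest.json"), simplifyVector = TRUE))
  digests <- vapply(mans, function(m) m$configDigest, "")
  if (length(unique(digests)) > 1L)
    .stopf(paste("refusing to merge: archive config digests differ",
                 "(incompatible channel order, normalization mode or patch",
                 "shape); re-segment with one configuration"))
  merged <- combinePatchSets(lapply(paths, readPatchArchive))
  writePatchArchive(merged, out)
}

# ---- model checkpoints -----------------------------------------------------

.model_tensors <- function(l)
  switch(l$type, conv = , fc = c("W", "b"),
         bn_conv = , bn_fc = c("gamma", "beta", "rmean", "rvar"),
         character(0))

#' Save a model checkpoint
#'
#' A checkpoint directory holds `spec.json` (architecture, class names,
#' freeze state, seed, provenance), `weights.bin` (all parameters including
#' batch-normalization running statistics, little-endian float64) and
#' `history.csv`.
#'
#' @param model a [TrainedModel-class].
#' @param dir checkpoint directory to create.
#' @param provenance optional named list recorded verbatim in `spec.json`
#'   (e.g. base-model digest for transfer models).
#' @return invisibly, `dir`.
#' @export
saveModel <- function(model, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- model@spec
  meta <- list(
    spec = list(inputChannels = s@inputChannels, inputSize = s@inputSize,
                nClasses = s@nClasses, convWidths = s@convWidths,
                kernelSizes = s@kernelSizes, fcWidths = s@fcWidths,
                poolSize = s@poolSize, poolStride = s@poolStride,
                dropoutRate = s@dropoutRate, padding = s@padding,
                widthScale = s@widthScale),
    classNames = model@classNames, frozenLayers = model@frozenLayers,
    frozenDigest = model@frozenDigest, seed = model@seed,
    provenance = provenance)
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (l in model@layers)
    for (p in .model_tensors(l))
      writeBin(as.numeric(l[[p]]), con, size = 8L, endian = "little")
  utils::write.csv(model@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint
#' @param dir directory written by [saveModel()].
#' @return the restored [TrainedModel-class].
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  s <- meta$spec
  spec <- networkSpec(nClasses = s$nClasses, inputChannels = s$inputChannels,
                      widthScale = s$widthScale, poolStride = s$poolStride,
                      padding = s$padding, inputSize = s$inputSize,
                      convWidths = s$convWidths, kernelSizes = s$kernelSizes,
                      fcWidths = s$fcWidths, poolSize = s$poolSize,
                      dropoutRate = s$dropoutRate)
  model <- buildNetwork(spec, classNames = meta$classNames,
                        seed = if (is.null(meta$seed)) 1L else meta$seed)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  for (i in seq_along(model@layers)) {
    l <- model@layers[[i]]
    for (p in .model_tensors(l)) {
      v <- readBin(con, "numeric", n = length(l[[p]]), size = 8L,
                   endian = "little")
      dim(v) <- dim(l[[p]])
      model@layers[[i]][[p]] <- v
    }
  }
  hist <- tryCatch(utils::read.csv(file.path(dir, "history.csv")),
                   error = function(e) data.frame())  # untrained: empty file
  if (nrow(hist)) model@history <- hist
  model@frozenLayers <- as.integer(meta$frozenLayers)
  model@frozenDigest <- if (is.null(meta$frozenDigest)) "" else
    meta$frozenDigest
  model
}

#' Per-class reference tallies and metrics of the eight-cell-line benchmark
#'
#' Small plain-text tables shipped with the package: per-class training and
#' testing counts of the reference eight-cell-line dataset, the per-class
#' test metrics of the reference classifier, and the per-class metrics of its
#' four-class transfer to a second microscope.  Used by the worked examples
#' and the reproduction script for balancing and macro-averaging arithmetic.
#'
#' @param which one of "training_counts", "test_metrics",
#'   "transfer_metrics".
#' @return a data.frame.
#' @export
referenceTable <- function(which = c("training_counts", "test_metrics",
                                     "transfer_metrics")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("cellline_", which, ".tsv"),
                      package = "phenocyte", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
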