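#' @include AllClasses.R utils.R
NULL

#' Segmentation configuration
#'
#' Tunable parameters of the detection and rejection cascade.
#'
#' @param minNucleusArea minimum nucleus component area (px) at frame level;
#'   removes hot pixels and specks.
#' @param patchMinArea minimum component area (px) for object counting inside
#'   a 75 x 75 patch.
#' @param viabilityFloor minimum Otsu-foreground pixel count in the cytoplasm
#'   channel for a cell to count as viable (pass iff count >= floor).
#' @param stainFloor minimum Otsu-foreground pixel count per fluorescent
#'   channel in the stain-presence test.
#' @param minContrastFrac operational definition of a "degenerate" channel: a
#'   raster is degenerate when the Otsu foreground/background mean separation
#'   is below this fraction of the full intensity range.  Plain Otsu marks
#'   roughly half the pixels of a pure-noise raster as foreground; this floor
#'   is what makes the viability and detection tests meaningful on
#'   signal-free channels.
#' @param watershedExt neighbourhood radius (px) for watershed seed
#'   suppression (minimum peak separation of distance-transform maxima).
#' @param watershedTolerance minimum basin depth for the watershed.
#' @param combineMode how the three fluorescent channels are combined for
#'   watershed object counting: "max" (pixelwise maximum of min-max scaled
#'   channels, default) or "sum".
#' @param normMode patch normalization: "bitdepth" (divide by
#'   2^bitDepth - 1, preserves relative intensity across patches; default) or
#'   "minmax" (per-patch, per-channel min-max).
#' @param otsuLevels histogram resolution used for Otsu thresholds.
#' @return a named list of settings.
#' @export
segmentationConfig <- function(minNucleusArea = 20L, patchMinArea = 20L,
                               viabilityFloor = 50L, stainFloor = 50L,
                               minContrastFrac = 0.05, watershedExt = 10,
                               watershedTolerance = 1,
                               combineMode = c("max", "sum"),
                               normMode = c("bitdepth", "minmax"),
                               otsuLevels = 256L) {
  list(minNucleusArea = minNucleusArea, patchMinArea = patchMinArea,
       viabilityFloor = viabilityFloor, stainFloor = stainFloor,
       minContrastFrac = minContrastFrac, watershedExt = watershedExt,
       watershedTolerance = watershedTolerance,
       combineMode = match.arg(combineMode), normMode = match.arg(normMode),
       otsuLevels = as.integer(otsuLevels))
}

#' Otsu intensity threshold
#'
#' Histogram threshold maximizing between-class variance; foreground is
#' defined as strictly greater than the returned threshold.
#'
#' @param raster numeric matrix with at least two distinct values.
#' @param levels histogram resolution.
#' @param range intensity range spanned by the histogram; defaults to the
#'   raster's own range.
#' @return the threshold (numeric scalar).
#' @export
otsuThreshold <- function(raster, levels = 256L, range = NULL) {
  if (!length(raster) || !all(is.finite(raster)))
    .stopf("raster must be nonempty and finite")
  r <- base::range(raster)
  if (r[1] == r[2])
    .stopf("degenerate input: raster is constant (value %g)", r[1])
  if (is.null(range)) range <- r
  as.numeric(EBImage::otsu(EBImage::Image(raster), range = range,
                           levels = as.integer(levels)))
}

# Otsu-binarize a raster with the degeneracy guard.  scaleMax is the full
# intensity range used for the contrast floor.  Returns list(mask, threshold,
# degenerate).
.binarize <- function(raster, config, scaleMax) {
  r <- range(raster)
  if (r[1] == r[2])
    return(list(mask = matrix(FALSE, nrow(raster), ncol(raster)),
                threshold = NA_real_, degenerate = TRUE))
  thr <- otsuThreshold(raster, levels = config$otsuLevels)
  fg <- raster > thr
  contrast <- mean(raster[fg]) - mean(raster[!fg])
  degenerate <- !any(fg) || all(fg) ||
    contrast < config$minContrastFrac * scaleMax
  if (degenerate) fg[] <- FALSE
  list(mask = fg, threshold = thr, degenerate = degenerate)
}

# 8-connected labeling with a minimum-area floor; returns the label matrix
# with small components removed (relabeled 1..K).
.label_mask <- function(mask, minArea) {
  lab <- .label_components8(mask)
  if (!max(lab)) return(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minArea)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Detect nuclei in the nuclear channel
#'
#' Binarizes the nuclear plane with a global Otsu threshold, labels
#' 8-connected components, drops components below `minNucleusArea`, and
#' returns component centroids.  A plane without genuine foreground/background
#' contrast (see `minContrastFrac` in [segmentationConfig()]) yields no
#' detections; a constant plane is an error.
#'
#' @param x a [WidefieldFrame-class], or a numeric matrix (nuclear plane).
#' @param config a [segmentationConfig()].
#' @param bitDepth bit depth when `x` is a bare matrix.
#' @return numeric matrix with columns row, col (1-based frame coordinates),
#'   one row per detected nucleus.
#' @export
detectNuclei <- function(x, config = segmentationConfig(), bitDepth = 14L) {
  if (is(x, "WidefieldFrame")) {
    bitDepth <- x@bitDepth
    x <- x@planes[, , 2]
  }
  scaleMax <- 2^bitDepth - 1
  r <- range(x)
  if (r[1] == r[2])
    .stopf("degenerate input: nuclear plane is constant (value %g)", r[1])
  b <- .binarize(x, config, scaleMax)
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (b$degenerate) return(empty)
  lab <- .label_mask(b$mask, config$minNucleusArea)
  k <- max(lab)
  if (!k) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  out <- cbind(row = as.numeric(tapply(idx[, 1], l, mean)),
               col = as.numeric(tapply(idx[, 2], l, mean)))
  rownames(out) <- NULL
  out
}

.round_half_up <- function(x) floor(x + 0.5)

.rejection <- function(centroid, reason) {
  structure(list(centroid = centroid, reason = reason), class = "rejection")
}

#' Is an object a rejection record?
#' @param x any object.
#' @return TRUE for a rejection record produced by the segmentation cascade.
#' @export
isRejection <- function(x) inherits(x, "rejection")

#' Extract a 75 x 75 candidate patch around a centroid
#'
#' The centroid is rounded to the nearest pixel (half away from zero) and a
#' 75 x 75 box is cropped around it; candidates whose box exceeds the frame
#' are returned as a border rejection.
#'
#' @param frame a [WidefieldFrame-class].
#' @param centroid numeric c(row, col), 1-based frame coordinates.
#' @param size patch edge (default 75).
#' @return a candidate patch (list with `pixels` 75x75x4 raw block,
#'   `centroid`, `fieldId`, `bitDepth`) or a rejection with reason
#'   `border_nucleus`.
#' @export
extractCandidate <- function(frame, centroid, size = 75L) {
  d <- dim(frame@planes)
  if (centroid[1] < 1 || centroid[1] > d[1] ||
      centroid[2] < 1 || centroid[2] > d[2])
    .stopf("centroid (%g, %g) lies outside the frame", centroid[1], centroid[2])
  half <- (size - 1L) %/% 2L
  r <- .round_half_up(centroid[1])
  c <- .round_half_up(centroid[2])
  if (r - half < 1 || r + half > d[1] || c - half < 1 || c + half > d[2])
    return(.rejection(centroid, "border_nucleus"))
  structure(list(
    pixels = frame@planes[(r - half):(r + half), (c - half):(c + half), ,
                          drop = FALSE],
    centroid = c(row = centroid[1], col = centroid[2]),
    fieldId = frame@fieldId, bitDepth = frame@bitDepth
  ), class = "candidatePatch")
}

#' Cell viability test
#'
#' Otsu-binarizes the candidate's cytoplasm channel and passes iff at least
#' `viabilityFloor` foreground pixels are present (boundary inclusive).  A
#' degenerate (near-constant) cytoplasm channel fails: the cell is assumed
#' dead.
#'
#' @param candidate a candidate patch from [extractCandidate()].
#' @param config a [segmentationConfig()].
#' @return logical pass/fail.
#' @export
viabilityTest <- function(candidate, config = segmentationConfig()) {
  scaleMax <- 2^candidate$bitDepth - 1
  b <- .binarize(candidate$pixels[, , 4], config, scaleMax)
  !b$degenerate && sum(b$mask) >= config$viabilityFloor
}

# border ring of a labeled/binary matrix
.on_border <- function(m) {
  any(m[1, ] > 0) || any(m[nrow(m), ] > 0) ||
    any(m[, 1] > 0) || any(m[, ncol(m)] > 0)
}

# min-max scale a matrix to [0, 1]
.minmax <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' Single-cell multiplicity test
#'
#' Rejects candidates containing more than one cell.  In order: (a) the
#' nuclear channel is Otsu-binarized and its objects counted (more than one
#' object fails with `multiple_nuclei`; nuclear foreground on the 1-px patch
#' border fails with `border_nucleus`); (b) the three fluorescent channels are
#' combined (pixelwise max of min-max scaled channels by default), binarized,
#' and a watershed seeded from distance-transform maxima counts cell bodies
#' (more than one basin, or a body touching the border, fails with
#' `multiple_bodies_watershed`); (c) the nuclear and cytoplasm channels are
#' each re-checked for a single object away from the border
#' (`multiple_nuclear_objects` / `multiple_cytoplasm_objects`); (d) the actin
#' channel is checked only for foreground on the border (`actin_on_border`),
#' since actin filaments may legitimately be disconnected.
#'
#' @param candidate a candidate patch that passed [viabilityTest()].
#' @param config a [segmentationConfig()].
#' @return list with `pass` (logical) and `reason` (NA when passing).
#' @export
multiplicityTest <- function(candidate, config = segmentationConfig()) {
  px <- candidate$pixels
  scaleMax <- 2^candidate$bitDepth - 1
  fail <- function(reason) list(pass = FALSE, reason = reason)

  # (a) nuclear object count and border contact
  bn <- .binarize(px[, , 2], config, scaleMax)
  if (bn$degenerate) return(fail("missing_stain"))
  ln <- .label_mask(bn$mask, config$patchMinArea)
  if (max(ln) > 1) return(fail("multiple_nuclei"))
  if (.on_border(ln)) return(fail("border_nucleus"))

  # (b) watershed body count on the combined fluorescent raster
  chans <- lapply(2:4, function(ch) .minmax(px[, , ch]))
  combined <- if (config$combineMode == "max")
    pmax(chans[[1]], chans[[2]], chans[[3]])
  else (chans[[1]] + chans[[2]] + chans[[3]]) / 3
  bc <- .binarize(combined, config, 1)
  if (bc$degenerate) return(fail("missing_stain"))
  body <- .label_mask(bc$mask, config$patchMinArea) > 0
  dm <- EBImage::distmap(EBImage::Image(body * 1))
  ws <- EBImage::imageData(EBImage::watershed(dm,
                                              tolerance = config$watershedTolerance,
                                              ext = config$watershedExt))
  if (max(ws) > 1 || .on_border(ws)) return(fail("multiple_bodies_watershed"))

  # (c) per-channel single-object/no-border checks
  lc <- .label_mask(.binarize(px[, , 4], config, scaleMax)$mask,
                    config$patchMinArea)
  if (max(ln) != 1 || .on_border(ln)) return(fail("multiple_nuclear_objects"))
  if (max(lc) > 1 || .on_border(lc)) return(fail("multiple_cytoplasm_objects"))

  # (d) actin: border contact only
  ba <- .binarize(px[, , 3], config, scaleMax)
  if (!ba$degenerate && .on_border(ba$mask)) return(fail("actin_on_border"))

  list(pass = TRUE, reason = NA_character_)
}

#' Stain presence test
#'
#' For each fluorescent channel (nuclear, actin, cytoplasm), requires the
#' channel to be non-degenerate and its Otsu foreground to contain at least
#' `stainFloor` pixels.
#'
#' @param candidate a candidate patch.
#' @param config a [segmentationConfig()].
#' @return logical pass/fail.
#' @export
stainPresenceTest <- function(candidate, config = segmentationConfig()) {
  scaleMax <- 2^candidate$bitDepth - 1
  for (ch in 2:4) {
    b <- .binarize(candidate$pixels[, , ch], config, scaleMax)
    if (b$degenerate || sum(b$mask) < config$stainFloor) return(FALSE)
  }
  TRUE
}

#' Normalize an accepted candidate to [0, 1]
#'
#' Default mode divides every channel by `2^bitDepth - 1`, preserving
#' relative intensity across patches; "minmax" rescales each channel of each
#' patch independently to [0, 1].
#'
#' @param candidate a candidate patch.
#' @param mode "bitdepth" or "minmax".
#' @return the candidate with `pixels` normalized and a `normMode` field.
#' @export
normalizePatch <- function(candidate, mode = c("bitdepth", "minmax")) {
  mode <- match.arg(mode)
  px <- candidate$pixels
  if (mode == "bitdepth") {
    px <- px / (2^candidate$bitDepth - 1)
  } else {
    for (ch in seq_len(dim(px)[3])) px[, , ch] <- .minmax(px[, , ch])
  }
  candidate$pixels <- px
  candidate$normMode <- mode
  candidate
}

#' Segment a widefield frame into quality-filtered single-cell patches
#'
#' Runs the full cascade: nucleus detection, candidate extraction, viability,
#' multiplicity (watershed), stain presence, and normalization, in that
#' order.  Each rejected candidate is logged with its first failing reason.
#'
#' @param frame a [WidefieldFrame-class].
#' @param config a [segmentationConfig()].
#' @return list with `patches` (an unlabeled [PatchSet-class] carrying
#'   centroid and field provenance) and `rejections` (data.frame with
#'   columns row, col, reason).
#' @export
segmentFrame <- function(frame, config = segmentationConfig()) {
  stopifnot(is(frame, "WidefieldFrame"))
  centroids <- tryCatch(detectNuclei(frame, config),
                        error = function(e)
                          .stopf("field '%s': %s", frame@fieldId,
                                 conditionMessage(e)))
  rej <- data.frame(row = numeric(0), col = numeric(0),
                    reason = character(0), stringsAsFactors = FALSE)
  accepted <- list()
  for (i in seq_len(nrow(centroids))) {
    ctr <- centroids[i, ]
    reject <- function(reason)
      rej <<- rbind(rej, data.frame(row = ctr[1], col = ctr[2],
                                    reason = reason, stringsAsFactors = FALSE))
    cand <- extractCandidate(frame, ctr)
    if (isRejection(cand)) { reject(cand$reason); next }
    if (!viabilityTest(cand, config)) { reject("nonviable"); next }
    mt <- multiplicityTest(cand, config)
    if (!mt$pass) { reject(mt$reason); next }
    if (!stainPresenceTest(cand, config)) { reject("missing_stain"); next }
    accepted[[length(accepted) + 1L]] <- normalizePatch(cand, config$normMode)
  }
  n <- length(accepted)
  size <- 75L
  px <- array(0, c(size, size, 4, n))
  ctrs <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(n)) {
    px[, , , i] <- accepted[[i]]$pixels
    ctrs[i, ] <- accepted[[i]]$centroid
  }
  patches <- PatchSet(px, centroids = ctrs,
                      fieldIds = rep(frame@fieldId, n),
                      normMode = config$normMode)
  list(patches = patches, rejections = rej)
}
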