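#' @include AllClasses.R utils.R
NULL

# Scene composition constants (raw 14-bit camera scale).  Fluorescent channels
# sit on a dark background; brightfield on a bright one.  Read noise is
# additive truncated-Gaussian; each sprite additionally carries multiplicative
# per-channel intensity jitter.
.phantom_defaults <- list(
  bit_depth = 14L,
  background = c(brightfield = 6000, nuclear = 120, actin = 120,
                 cytoplasm = 120),
  noise_sd = 60,
  jitter_sd = 0.08,
  patch_size = 75L,
  border_margin = 38L
)

#' Construct phantom class parameters
#'
#' @param className class name.
#' @param nucleusRadius c(mean, sd) nucleus radius in px.
#' @param cytoplasmRadius c(mean, sd) cytoplasm radius in px; mean must exceed
#'   the nucleus mean.
#' @param actinTextureScale spatial scale (px) of the actin texture.
#' @param channelIntensityMeans mean foreground intensity per channel
#'   (brightfield ring, nuclear, actin, cytoplasm) on the raw camera scale.
#' @param eccentricity nuclear eccentricity in [0, 1).
#' @return a [PhantomClassParams-class].
#' @export
PhantomClassParams <- function(className, nucleusRadius, cytoplasmRadius,
                               actinTextureScale, channelIntensityMeans,
                               eccentricity = 0) {
  new("PhantomClassParams", className = className,
      nucleusRadius = as.numeric(nucleusRadius),
      cytoplasmRadius = as.numeric(cytoplasmRadius),
      actinTextureScale = as.numeric(actinTextureScale),
      channelIntensityMeans = as.numeric(channelIntensityMeans),
      eccentricity = as.numeric(eccentricity))
}

#' Built-in eight-class phantom preset
#'
#' Eight cell-class recipes with graded similarity: two pairs of
#' "leukemia-like" classes (`lymphoid_a`/`lymphoid_b` and
#' `monocytic_a`/`monocytic_b`) are deliberately close in every parameter so
#' that classifiers confuse them preferentially, exercising a realistic
#' confusion structure; the remaining classes are well separated.
#'
#' @return named list of [PhantomClassParams-class].
#' @export
phantomClassPreset <- function() {
  p <- list(
    PhantomClassParams("lymphoid_a",   c(6.0, 0.5), c(10.0, 0.8), 1.5,
                       c(2500, 11000, 5000, 6500), 0.05),
    PhantomClassParams("lymphoid_b",   c(6.3, 0.5), c(10.5, 0.8), 1.7,
                       c(2500, 10500, 5200, 6800), 0.05),
    PhantomClassParams("monocytic_a",  c(7.5, 0.6), c(12.0, 1.0), 2.5,
                       c(2600, 9000, 6500, 8000), 0.10),
    PhantomClassParams("monocytic_b",  c(7.8, 0.6), c(12.5, 1.0), 2.7,
                       c(2600, 8800, 6800, 8200), 0.10),
    PhantomClassParams("epithelial_small", c(8.0, 0.7), c(13.0, 1.0), 3.5,
                       c(2800, 12000, 8000, 9500), 0.20),
    PhantomClassParams("epithelial_large", c(10.0, 0.8), c(16.0, 1.2), 4.0,
                       c(3000, 13000, 9000, 11000), 0.25),
    PhantomClassParams("sarcoma_like", c(9.0, 0.8), c(14.0, 1.2), 5.0,
                       c(2700, 7500, 10000, 7000), 0.35),
    PhantomClassParams("large_round",  c(11.0, 0.8), c(17.0, 1.2), 2.0,
                       c(3200, 14000, 6000, 12000), 0.05)
  )
  names(p) <- vapply(p, slot, character(1), "className")
  p
}

#' Four widely separated phantom classes
#'
#' A deliberately easy 4-class configuration with large inter-class distance
#' in every morphology and intensity parameter, for learning-sanity checks:
#' on data generated from it, even a channel-mean nearest-centroid classifier
#' exceeds 0.95 accuracy, so a trained network is expected to as well.
#'
#' @return named list of four [PhantomClassParams-class].
#' @export
phantomSeparablePreset <- function() {
  p <- list(
    PhantomClassParams("small_dim",    c(6, 0.5),  c(10, 0.8),   1.5,
                       c(2500, 6000, 4000, 5000), 0.05),
    PhantomClassParams("medium_mixed", c(8, 0.6),  c(12.5, 0.9), 3.0,
                       c(2700, 9500, 7000, 8000), 0.15),
    PhantomClassParams("large_textured", c(10, 0.7), c(15, 1.0), 4.5,
                       c(2900, 13000, 10000, 11000), 0.25),
    PhantomClassParams("giant_bright", c(12, 0.8), c(17, 1.1),   2.2,
                       c(3100, 15500, 5500, 14000), 0.05)
  )
  names(p) <- vapply(p, slot, character(1), "className")
  p
}

#' Four-class preset with class signal only in the fluorescent channels
#'
#' All four classes share identical geometry (nucleus/cytoplasm radii,
#' eccentricity) and brightfield intensity; they differ only in fluorescent
#' intensities and actin texture.  A brightfield-only classifier therefore
#' has no class signal beyond noise, while fluorescent channels separate the
#' classes well.
#'
#' @return named list of four [PhantomClassParams-class].
#' @export
phantomFluorescentPreset <- function() {
  geom <- list(nuc = c(8, 0.6), cyt = c(13, 0.9), ecc = 0.1, bf = 2600)
  p <- list(
    PhantomClassParams("fluor_a", geom$nuc, geom$cyt, 1.5,
                       c(geom$bf, 9000, 5000, 6500), geom$ecc),
    PhantomClassParams("fluor_b", geom$nuc, geom$cyt, 2.5,
                       c(geom$bf, 12500, 6500, 9000), geom$ecc),
    PhantomClassParams("fluor_c", geom$nuc, geom$cyt, 3.5,
                       c(geom$bf, 10500, 9000, 11500), geom$ecc),
    PhantomClassParams("fluor_d", geom$nuc, geom$cyt, 2.8,
                       c(geom$bf, 14000, 7500, 8000), geom$ecc)
  )
  names(p) <- vapply(p, slot, character(1), "className")
  p
}

#' Shrink or restore inter-class separation of a preset
#'
#' Interpolates every class parameter toward the across-class mean:
#' `factor = 1` leaves the preset unchanged, `factor = 0` collapses all
#' classes onto their common mean.  Used to dial class separability when
#' probing classifier behaviour.
#'
#' @param classes list of [PhantomClassParams-class].
#' @param factor interpolation factor in [0, 1].
#' @return list of adjusted [PhantomClassParams-class].
#' @export
scaleSeparation <- function(classes, factor) {
  stopifnot(factor >= 0, factor <= 1)
  m_nuc <- mean(vapply(classes, function(p) p@nucleusRadius[1], 0))
  m_cyt <- mean(vapply(classes, function(p) p@cytoplasmRadius[1], 0))
  m_act <- mean(vapply(classes, function(p) p@actinTextureScale, 0))
  m_ecc <- mean(vapply(classes, function(p) p@eccentricity, 0))
  m_int <- rowMeans(vapply(classes, function(p) p@channelIntensityMeans,
                           numeric(4)))
  lapply(classes, function(p) {
    PhantomClassParams(
      p@className,
      c(m_nuc + factor * (p@nucleusRadius[1] - m_nuc), p@nucleusRadius[2]),
      c(m_cyt + factor * (p@cytoplasmRadius[1] - m_cyt), p@cytoplasmRadius[2]),
      m_act + factor * (p@actinTextureScale - m_act),
      m_int + factor * (p@channelIntensityMeans - m_int),
      m_ecc + factor * (p@eccentricity - m_ecc))
  })
}

# Core sprite renderer; must run inside a seeded RNG context.
# Returns additive foreground contributions (no background, no read noise).
.render_cell <- function(params, size = 75L) {
  validObject(params)
  ctr <- (size + 1) / 2
  rn <- max(2, stats::rnorm(1, params@nucleusRadius[1], params@nucleusRadius[2]))
  rc <- max(rn + 2,
            stats::rnorm(1, params@cytoplasmRadius[1], params@cytoplasmRadius[2]))
  theta <- stats::runif(1, 0, pi)
  jit <- pmin(pmax(stats::rnorm(4, 1, .phantom_defaults$jitter_sd), 0.5), 1.5)
  ints <- params@channelIntensityMeans * jit

  xs <- matrix(seq_len(size) - ctr, size, size)         # row offsets
  ys <- matrix(seq_len(size) - ctr, size, size, byrow = TRUE)
  e2 <- params@eccentricity^2
  a <- rn / (1 - e2)^0.25                                # area-preserving axes
  b <- rn * (1 - e2)^0.25
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  nucleus_mask <- (u / a)^2 + (v / b)^2 <= 1
  dist <- sqrt(xs^2 + ys^2)
  cyto_mask <- dist <= rc

  speckle <- function() pmax(matrix(stats::rnorm(size * size, 1, 0.05),
                                    size, size), 0)
  planes <- array(0, c(size, size, 4))
  # brightfield analog: a faint halo ring at the cell boundary
  ring <- abs(dist - rc) <= 1.5
  planes[, , 1][ring] <- (ints[1] * speckle())[ring]
  planes[, , 2][nucleus_mask] <- (ints[2] * speckle())[nucleus_mask]
  if (ints[3] > 0) {
    field <- matrix(stats::runif(size * size), size, size)
    field <- EBImage::imageData(
      EBImage::gblur(EBImage::Image(field), sigma = params@actinTextureScale))
    rng <- range(field)
    field <- if (diff(rng) > 0) (field - rng[1]) / diff(rng) else field * 0
    planes[, , 3][cyto_mask] <- (ints[3] * (0.3 + 1.4 * field))[cyto_mask]
  }
  if (ints[4] > 0)
    planes[, , 4][cyto_mask] <- (ints[4] * speckle())[cyto_mask]
  list(planes = planes, nucleusMask = nucleus_mask, cytoplasmMask = cyto_mask,
       nucleusRadius = rn, cytoplasmRadius = rc)
}

#' Render one phantom cell sprite
#'
#' Produces a 4-plane sprite (additive foreground contributions on the raw
#' camera scale, without background or read noise) together with the nucleus
#' and cytoplasm boolean masks.  Plane order: brightfield halo ring, nuclear
#' ellipse, actin texture over the cytoplasm, filled cytoplasm.
#'
#' @param params a [PhantomClassParams-class].
#' @param seed integer seed; the sprite is a pure function of
#'   (params, seed, size).
#' @param size sprite canvas edge in px (default 75).
#' @return list with `planes` (size x size x 4 array), `nucleusMask`,
#'   `cytoplasmMask`, and the drawn `nucleusRadius` / `cytoplasmRadius`.
#' @export
renderCell <- function(params, seed, size = 75L) {
  .with_seed(seed, .render_cell(params, size = size))
}

# add a sprite's planes onto frame planes, clipping at frame borders
.paste_sprite <- function(planes, sprite, r, c) {
  sz <- dim(sprite)[1]
  half <- (sz - 1) / 2
  H <- dim(planes)[1]; W <- dim(planes)[2]
  r0 <- r - half; c0 <- c - half
  fr <- max(1, r0):min(H, r0 + sz - 1)
  fc <- max(1, c0):min(W, c0 + sz - 1)
  sr <- fr - r0 + 1; sc <- fc - c0 + 1
  planes[fr, fc, ] <- planes[fr, fc, , drop = FALSE] +
    sprite[sr, sc, , drop = FALSE]
  planes
}

#' Generate a synthetic widefield scene with ground truth
#'
#' Places phantom objects in a frame with rejection-aware geometry: viable
#' cells sit at least `minSpacing` px apart and away from borders; border
#' cells have centroids closer than 38 px to an edge; doublets are two
#' disjoint nuclei inside one 75 x 75 window; dead cells carry no cytoplasm
#' signal; debris are small fluorescent specks without a nucleus/cytoplasm
#' pair.  Additive truncated-Gaussian read noise is applied to all planes.
#'
#' @param classes list of [PhantomClassParams-class] used (round-robin) for
#'   the viable cells and as body recipes for the rejectable objects.
#' @param counts named numeric vector with any of the kinds
#'   `viable_cell`, `doublet`, `dead_cell`, `debris`, `border_cell`.
#' @param frameShape c(H, W) in px (default 1212 x 1212, quarter-scale of a
#'   2424 x 2424 camera field, for speed; pass the full size if wanted).
#' @param minSpacing minimum centroid spacing between objects in px.
#' @param seed integer seed.
#' @param fieldId field identifier stored in the frame.
#' @return a [PhantomScene-class].
#' @export
makeScene <- function(classes, counts, frameShape = c(1212L, 1212L),
                      minSpacing = 110, seed = 1L, fieldId = "phantom_field") {
  if (is(classes, "PhantomClassParams")) classes <- list(classes)
  counts <- counts[counts > 0]
  bad <- setdiff(names(counts), .scene_kinds)
  if (length(bad)) .stopf("unknown object kind(s): %s", paste(bad, collapse = ", "))
  H <- as.integer(frameShape[1]); W <- as.integer(frameShape[2])
  margin <- .phantom_defaults$border_margin + 22L  # keep whole body in-frame
  if (2L * margin >= min(H, W))
    .stopf("placement error: frame %dx%d too small for interior margin %d",
           H, W, margin)
  def <- .phantom_defaults
  .with_seed(seed, {
    bg <- def$background
    planes <- array(0, c(H, W, 4))
    noise <- pmin(pmax(stats::rnorm(H * W * 4, 0, def$noise_sd),
                       -3 * def$noise_sd), 3 * def$noise_sd)
    for (ch in 1:4) planes[, , ch] <- bg[ch]
    planes <- planes + array(noise, c(H, W, 4))

    placed <- matrix(numeric(0), 0, 2)
    truth <- data.frame(row = numeric(0), col = numeric(0),
                        kind = character(0), class = character(0),
                        stringsAsFactors = FALSE)
    draw_pos <- function(kind) {
      for (i in seq_len(2000L)) {
        if (kind == "border_cell") {
          edge <- sample(4L, 1L)
          d <- stats::runif(1, 10, 30)
          pos <- switch(edge,
            c(d, stats::runif(1, margin, W - margin)),
            c(H - d, stats::runif(1, margin, W - margin)),
            c(stats::runif(1, margin, H - margin), d),
            c(stats::runif(1, margin, H - margin), W - d))
        } else {
          pos <- c(stats::runif(1, margin, H - margin),
                   stats::runif(1, margin, W - margin))
        }
        if (!nrow(placed) ||
            min(sqrt(colSums((t(placed) - pos)^2))) >= minSpacing)
          return(pos)
      }
      .stopf("placement error: could not satisfy min_spacing=%g for kind '%s'",
             minSpacing, kind)
    }

    ci <- 0L
    next_class <- function() {
      ci <<- ci %% length(classes) + 1L
      classes[[ci]]
    }
    add_truth <- function(pos, kind, class = NA_character_) {
      placed <<- rbind(placed, pos)
      truth <<- rbind(truth, data.frame(row = pos[1], col = pos[2],
                                        kind = kind, class = class,
                                        stringsAsFactors = FALSE))
    }

    for (kind in names(counts)) {
      for (i in seq_len(counts[[kind]])) {
        pos <- draw_pos(kind)
        p <- next_class()
        if (kind %in% c("viable_cell", "border_cell")) {
          sp <- .render_cell(p)
          planes <- .paste_sprite(planes, sp$planes, round(pos[1]), round(pos[2]))
          add_truth(pos, kind, if (kind == "viable_cell") p@className
                               else NA_character_)
        } else if (kind == "dead_cell") {
          pd <- p
          pd@channelIntensityMeans[4] <- 0          # no viability stain
          pd@channelIntensityMeans[3] <- 0.2 * pd@channelIntensityMeans[3]
          sp <- .render_cell(pd)
          planes <- .paste_sprite(planes, sp$planes, round(pos[1]), round(pos[2]))
          add_truth(pos, kind)
        } else if (kind == "doublet") {
          s1 <- .render_cell(p)
          s2 <- .render_cell(p)
          gap <- s1$nucleusRadius + s2$nucleusRadius + 4  # disjoint nuclei
          ang <- stats::runif(1, 0, 2 * pi)
          off <- gap / 2 * c(cos(ang), sin(ang))
          planes <- .paste_sprite(planes, s1$planes,
                                  round(pos[1] - off[1]), round(pos[2] - off[2]))
          planes <- .paste_sprite(planes, s2$planes,
                                  round(pos[1] + off[1]), round(pos[2] + off[2]))
          add_truth(pos, kind)
        } else if (kind == "debris") {
          sz <- 15L
          spk <- array(0, c(sz, sz, 4))
          xs <- matrix(seq_len(sz) - 8, sz, sz)
          ys <- t(xs)
          blob <- sqrt(xs^2 + ys^2) <= stats::runif(1, 2, 4)
          lvl <- stats::runif(1, 3000, 9000)
          spk[, , 3][blob] <- lvl
          spk[, , 4][blob] <- 0.7 * lvl
          planes <- .paste_sprite(planes, spk, round(pos[1]), round(pos[2]))
          add_truth(pos, kind)
        }
      }
    }
    maxv <- 2^def$bit_depth - 1
    planes <- round(pmin(pmax(planes, 0), maxv))
    frame <- new("WidefieldFrame", planes = planes,
                 bitDepth = def$bit_depth, fieldId = fieldId)
    new("PhantomScene", frame = frame, truth = truth)
  })
}

#' Render a labeled patch dataset directly (bypassing segmentation)
#'
#' Renders centered single-cell patches for each class, adds background and
#' read noise, and normalizes with the same rule as the segmentation module
#' (division by the bit-depth maximum by default).  A small integer centroid
#' jitter (+/- `jitterPx`) emulates centroid rounding error.
#'
#' @param classes list of [PhantomClassParams-class].
#' @param nPerClass patches per class (>= 1).
#' @param seed integer seed.
#' @param jitterPx maximum absolute centering jitter in px.
#' @param normMode "bitdepth" or "minmax" (see [normalizePatch()]).
#' @return a labeled [PatchSet-class] of 75 x 75 x 4 patches in [0, 1].
#' @export
makePatchDataset <- function(classes, nPerClass, seed = 1L, jitterPx = 2L,
                             normMode = c("bitdepth", "minmax")) {
  normMode <- match.arg(normMode)
  if (is(classes, "PhantomClassParams")) classes <- list(classes)
  if (nPerClass < 1) .stopf("nPerClass must be >= 1")
  def <- .phantom_defaults
  size <- def$patch_size
  maxv <- 2^def$bit_depth - 1
  n <- length(classes) * nPerClass
  .with_seed(seed, {
    px <- array(0, c(size, size, 4, n))
    labels <- character(n)
    i <- 0L
    for (p in classes) {
      for (k in seq_len(nPerClass)) {
        i <- i + 1L
        sp <- .render_cell(p, size = size)
        canvas <- array(rep(def$background, each = size * size),
                        c(size, size, 4)) +
          array(pmin(pmax(stats::rnorm(size * size * 4, 0, def$noise_sd),
                          -3 * def$noise_sd), 3 * def$noise_sd),
                c(size, size, 4))
        dr <- sample(-jitterPx:jitterPx, 1)
        dc <- sample(-jitterPx:jitterPx, 1)
        canvas <- .paste_sprite(canvas, sp$planes,
                                (size + 1) / 2 + dr, (size + 1) / 2 + dc)
        raw <- round(pmin(pmax(canvas, 0), maxv))
        px[, , , i] <- if (normMode == "bitdepth") raw / maxv else {
          for (ch in 1:4) {
            v <- raw[, , ch]
            rng <- range(v)
            raw[, , ch] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0
          }
          raw
        }
        labels[i] <- p@className
      }
    }
    PatchSet(px, labels = labels,
             fieldIds = rep("phantom_patch", n), normMode = normMode)
  })
}

#' Label segmented patches from scene ground truth
#'
#' Matches each patch centroid to the nearest ground-truth record; patches
#' within `maxDist` px of a viable cell inherit its class name, all others
#' get NA.
#'
#' @param patches a [PatchSet-class] from [segmentFrame()].
#' @param truth a truth data.frame (see [sceneTruth()]), or a
#'   [PhantomScene-class].
#' @param maxDist maximum centroid distance in px.
#' @return the [PatchSet-class] with labels filled in.
#' @export
assignTruthLabels <- function(patches, truth, maxDist = 5) {
  if (is(truth, "PhantomScene")) truth <- sceneTruth(truth)
  n <- nPatches(patches)
  if (!n || !nrow(truth)) return(patches)
  labels <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    d <- sqrt((truth$row - patches@centroids[i, 1])^2 +
              (truth$col - patches@centroids[i, 2])^2)
    j <- which.min(d)
    if (d[j] <= maxDist && truth$kind[j] == "viable_cell")
      labels[i] <- truth$class[j]
  }
  patchLabels(patches) <- labels
  patches
}
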