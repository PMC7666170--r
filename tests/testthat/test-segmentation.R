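# independent oracle: exhaustive scan over candidate thresholds maximizing
# between-class variance on the raw values
otsu_oracle <- function(x) {
  vals <- sort(unique(as.numeric(x)))
  cuts <- (vals[-1] + vals[-length(vals)]) / 2
  bcv <- vapply(cuts, function(t) {
    w1 <- mean(x <= t)
    if (w1 == 0 || w1 == 1) return(0)
    (mean(x[x <= t]) - mean(x[x > t]))^2 * w1 * (1 - w1)
  }, 0)
  cuts[which.max(bcv)]
}

test_that("otsu threshold separates modes and rejects constant rasters", {
  x <- matrix(c(rep(0, 100), rep(100, 100)), 10, 20)
  thr <- otsuThreshold(x)
  expect_equal(sum(x > thr), 100L)
  expect_gt(thr, 0)
  expect_lt(thr, 100)

  set.seed(31)
  y <- matrix(c(rnorm(5000, 200, 50), rnorm(5000, 2000, 50)), 100, 100)
  thr2 <- otsuThreshold(y)
  expect_gt(thr2, 350)
  expect_lt(thr2, 1850)
  # the binned threshold agrees with the exhaustive-scan oracle's partition
  expect_equal(sum(y > thr2), sum(y > otsu_oracle(y)))

  expect_error(otsuThreshold(matrix(7, 5, 5)), "degenerate")
})

test_that("nucleus detection matches ground truth and ignores pure noise", {
  scene <- fixture("det_scene",
                   makeScene(phantomClassPreset(),
                             c(viable_cell = 20), seed = 8))
  truth <- sceneTruth(scene)
  found <- detectNuclei(sceneFrame(scene))
  expect_equal(nrow(found), 20L)
  dists <- vapply(seq_len(nrow(found)), function(i)
    min(sqrt((truth$row - found[i, 1])^2 + (truth$col - found[i, 2])^2)), 0)
  expect_lt(max(dists), 2)

  noise <- makeScene(phantomClassPreset(), c(viable_cell = 0),
                     frameShape = c(300L, 300L), seed = 2)
  expect_equal(nrow(detectNuclei(sceneFrame(noise))), 0L)

  # two merged nuclei are one connected component, hence one centroid
  plane <- matrix(100, 200, 200)
  xs <- row(plane); ys <- col(plane)
  plane[sqrt((xs - 100)^2 + (ys - 95)^2) < 8] <- 12000
  plane[sqrt((xs - 100)^2 + (ys - 107)^2) < 8] <- 12000
  expect_equal(nrow(detectNuclei(plane + rnorm(length(plane)), bitDepth = 14L)),
               1L)
})

test_that("candidate extraction crops, rounds and rejects borders", {
  planes <- array(rep(1:4, each = 75 * 75), c(75, 75, 4))
  fr <- new("WidefieldFrame", planes = planes, bitDepth = 14L, fieldId = "f")
  cand <- extractCandidate(fr, c(38, 38))
  expect_identical(cand$pixels, planes)

  big <- new("WidefieldFrame", planes = array(0, c(1212, 1212, 4)),
             bitDepth = 14L, fieldId = "f")
  rej <- extractCandidate(big, c(11, 500))
  expect_true(isRejection(rej))
  expect_equal(rej$reason, "border_nucleus")

  # rounding is half-away-from-zero: 100.6 -> 101, 200.2 -> 200, 50.5 -> 51
  marked <- big
  marked@planes[101, 200, 1] <- 42
  cand2 <- extractCandidate(marked, c(100.6, 200.2))
  expect_equal(cand2$pixels[38, 38, 1], 42)
  marked@planes[51, 51, 1] <- 43
  cand3 <- extractCandidate(marked, c(50.5, 50.5))
  expect_equal(cand3$pixels[38, 38, 1], 43)

  expect_error(extractCandidate(big, c(-4, 10)), "outside")
})

test_that("viability is an inclusive 50-pixel floor on cytoplasm foreground", {
  make_cand <- function(n_fg) {
    px <- array(0, c(75, 75, 4))
    px[, , 4] <- 100
    if (n_fg > 0) px[, , 4][seq_len(n_fg)] <- 12000
    structure(list(pixels = px, centroid = c(38, 38), fieldId = "t",
                   bitDepth = 14L), class = "candidatePatch")
  }
  expect_false(viabilityTest(make_cand(49)))
  expect_true(viabilityTest(make_cand(50)))

  set.seed(5)
  expect_false(viabilityTest(sprite_candidate(phantomClassPreset()$lymphoid_a,
                                              seed = 3, dead = TRUE)))
  live <- sprite_candidate(phantomClassPreset()$monocytic_a, seed = 3)
  expect_true(viabilityTest(live))
  # foreground count is close to the generator's cytoplasm mask area
  sp <- renderCell(phantomClassPreset()$monocytic_a, seed = 3)
  b <- phenocyte:::.binarize(live$pixels[, , 4], segmentationConfig(),
                             2^14 - 1)
  expect_lt(abs(sum(b$mask) - sum(sp$cytoplasmMask)) / sum(sp$cytoplasmMask),
            0.15)
})

test_that("multiplicity testing accepts single centered cells and flags others", {
  set.seed(6)
  single <- sprite_candidate(phantomClassPreset()$epithelial_small, seed = 12)
  mt <- multiplicityTest(single)
  expect_true(mt$pass)

  # actin reaching the border is rejected with the actin-specific reason
  touched <- single
  touched$pixels[1, 30:40, 3] <- 9000
  mt2 <- multiplicityTest(touched)
  expect_false(mt2$pass)
  expect_equal(mt2$reason, "actin_on_border")

  # second cytoplasm body (no extra nucleus) trips the watershed/body checks
  deb <- single
  xs <- row(matrix(0, 75, 75)); ys <- col(matrix(0, 75, 75))
  blob <- sqrt((xs - 12)^2 + (ys - 62)^2) < 6
  deb$pixels[, , 4][blob] <- 11000
  mt3 <- multiplicityTest(deb)
  expect_false(mt3$pass)
  expect_true(mt3$reason %in% c("multiple_bodies_watershed",
                                "multiple_cytoplasm_objects"))
})

test_that("watershed body counts match component counts for separated objects", {
  set.seed(44)
  for (i in 1:5) {
    n_obj <- sample(1:3, 1)
    px <- array(0, c(75, 75, 4))
    px[, , 2:4] <- 100
    centers <- list(c(20, 20), c(55, 55), c(20, 58))[seq_len(n_obj)]
    xs <- row(matrix(0, 75, 75)); ys <- col(matrix(0, 75, 75))
    for (ct in centers) {
      disk <- sqrt((xs - ct[1])^2 + (ys - ct[2])^2) < 8
      for (ch in 2:4) px[, , ch][disk] <- 11000
    }
    cand <- structure(list(pixels = px, centroid = c(38, 38), fieldId = "t",
                           bitDepth = 14L), class = "candidatePatch")
    combined <- pmax(phenocyte:::.minmax(px[, , 2]),
                     phenocyte:::.minmax(px[, , 3]),
                     phenocyte:::.minmax(px[, , 4]))
    comp <- max(phenocyte:::.label_components8(combined > 0.5))
    expect_equal(comp, n_obj)
    mt <- multiplicityTest(cand)
    expect_equal(mt$pass, n_obj == 1L)
  }
})

test_that("stain presence needs every fluorescent channel at its floor", {
  set.seed(7)
  good <- sprite_candidate(phantomClassPreset()$monocytic_b, seed = 9)
  expect_true(stainPresenceTest(good))

  noactin <- good
  noactin$pixels[, , 3] <- 0
  expect_false(stainPresenceTest(noactin))

  # exactly floor-count foreground pixels pass (inclusive)
  floor_cand <- good
  floor_cand$pixels[, , 3] <- 100
  floor_cand$pixels[, , 3][seq_len(50)] <- 12000
  expect_true(stainPresenceTest(floor_cand))
  floor_cand$pixels[, , 3][50] <- 100
  expect_false(stainPresenceTest(floor_cand))
})

test_that("normalization maps the camera range onto [0, 1]", {
  cand <- structure(list(pixels = array(16383, c(75, 75, 4)),
                         centroid = c(38, 38), fieldId = "t",
                         bitDepth = 14L), class = "candidatePatch")
  expect_equal(range(normalizePatch(cand)$pixels), c(1, 1))
  cand$pixels[] <- 0
  expect_equal(range(normalizePatch(cand)$pixels), c(0, 0))
  cand$pixels[] <- 8191
  expect_equal(normalizePatch(cand)$pixels[1, 1, 1], 8191 / 16383)
  cand$pixels[1, 1, 1] <- 16383
  mm <- normalizePatch(cand, "minmax")
  expect_equal(range(mm$pixels[, , 1]), c(0, 1))
})

test_that("frame segmentation accepts the viable cells and logs first-failure reasons", {
  seg <- acceptance_segmentation()
  expect_equal(nPatches(seg$patches), 20L)
  tally <- table(seg$rejections$reason)
  multiplicity <- sum(tally[names(tally) %in%
    c("multiple_nuclei", "multiple_bodies_watershed",
      "multiple_nuclear_objects", "multiple_cytoplasm_objects")])
  expect_gte(multiplicity, 5L)
  expect_gte(sum(tally["nonviable"], na.rm = TRUE), 5L)
  expect_gte(sum(tally["border_nucleus"], na.rm = TRUE), 3L)

  # accepted + rejected equals detections
  dets <- detectNuclei(sceneFrame(acceptance_scene()))
  expect_equal(nPatches(seg$patches) + nrow(seg$rejections), nrow(dets))

  # every accepted patch satisfies the patch contract and has one nucleus
  px <- patchPixels(seg$patches)
  expect_true(all(is.finite(px)) && min(px) >= 0 && max(px) <= 1)
  cfg <- segmentationConfig()
  for (i in seq_len(nPatches(seg$patches))) {
    b <- phenocyte:::.binarize(px[, , 2, i], cfg, 1)
    lab <- phenocyte:::.label_mask(b$mask, cfg$patchMinArea)
    expect_equal(max(lab), 1L)
  }

  # determinism: same frame, same config, identical output
  seg2 <- segmentFrame(sceneFrame(acceptance_scene()))
  expect_identical(seg2$patches@pixels, seg$patches@pixels)
  expect_identical(seg2$rejections, seg$rejections)
})

test_that("raising generator spacing never lowers the accepted fraction", {
  fracs <- vapply(c(90, 130), function(sp) {
    scene <- makeScene(phantomClassPreset()[1:4], c(viable_cell = 10),
                       frameShape = c(900L, 900L), minSpacing = sp, seed = 3)
    seg <- segmentFrame(sceneFrame(scene))
    labeled <- assignTruthLabels(seg$patches, scene)
    sum(!is.na(patchLabels(labeled))) / 10
  }, 0)
  expect_gte(fracs[2], fracs[1])
})

test_that("degenerate frames error with field context", {
  fr <- new("WidefieldFrame", planes = array(5, c(100, 100, 4)),
            bitDepth = 14L, fieldId = "flatfield")
  expect_error(segmentFrame(fr), "flatfield")
})
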