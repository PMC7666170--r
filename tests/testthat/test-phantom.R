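test_that("sprite rendering is deterministic and parameter-faithful", {
  p <- phantomClassPreset()$monocytic_a
  s1 <- renderCell(p, seed = 5)
  s2 <- renderCell(p, seed = 5)
  expect_identical(s1, s2)
  s3 <- renderCell(p, seed = 6)
  expect_false(identical(s1$planes, s3$planes))

  # a zero cytoplasm intensity produces an empty viability plane (dead cell)
  dead <- p
  dead@channelIntensityMeans[4] <- 0
  sd1 <- renderCell(dead, seed = 5)
  expect_identical(sum(sd1$planes[, , 4] != 0), 0L)

  # an sd-0, eccentricity-0 nucleus of radius 8 is a pixelated disk of
  # area ~ pi * 8^2
  disk <- PhantomClassParams("disk", c(8, 0), c(14, 0), 2,
                             c(2500, 11000, 5000, 6500), 0)
  area <- sum(renderCell(disk, seed = 1)$nucleusMask)
  expect_lt(abs(area - pi * 64) / (pi * 64), 0.05)
})

test_that("class parameter invariants are enforced", {
  expect_error(PhantomClassParams("x", c(10, 0.5), c(8, 0.5), 2,
                                  c(1, 1, 1, 1), 0),
               "cytoplasm")
  expect_error(PhantomClassParams("x", c(5, 0.5), c(9, 0.5), 2,
                                  c(1, 1, 1, 1), 1.2),
               "eccentricity")
  expect_error(PhantomClassParams("x", c(-1, 0.5), c(9, 0.5), 2,
                                  c(1, 1, 1, 1), 0),
               "nucleusRadius")
})

test_that("scene generation keeps truth bookkeeping and responds to seeds", {
  scene <- acceptance_scene()
  truth <- sceneTruth(scene)
  expect_equal(nrow(truth), 33L)
  tally <- table(truth$kind)
  expect_equal(as.integer(tally[c("viable_cell", "doublet", "dead_cell",
                                  "border_cell")]),
               c(20L, 5L, 5L, 3L))
  expect_true(all(!is.na(truth$class[truth$kind == "viable_cell"])))
  expect_true(all(is.na(truth$class[truth$kind != "viable_cell"])))
  d <- dim(framePlanes(sceneFrame(scene)))
  expect_true(all(truth$row >= 1 & truth$row <= d[1]))

  other <- makeScene(phantomClassPreset(),
                     c(viable_cell = 20, doublet = 5, dead_cell = 5,
                       border_cell = 3), seed = 12)
  expect_false(identical(sceneTruth(other)$row, truth$row))

  empty <- makeScene(phantomClassPreset(), c(viable_cell = 0), seed = 1)
  expect_equal(nrow(sceneTruth(empty)), 0L)
})

test_that("infeasible placement fails with a named constraint", {
  expect_error(makeScene(phantomClassPreset()[1:2], c(viable_cell = 400),
                         frameShape = c(500L, 500L), minSpacing = 110,
                         seed = 1),
               "min_spacing")
})

test_that("patch datasets are normalized, labeled and reproducible", {
  classes <- sep4_classes()
  ds <- small4_dataset()
  expect_equal(dim(patchPixels(ds)), c(75L, 75L, 4L, 200L))
  expect_true(min(patchPixels(ds)) >= 0 && max(patchPixels(ds)) <= 1)
  expect_equal(as.integer(table(patchLabels(ds))), rep(50L, 4))

  # per-class cytoplasm-channel means are ordered as configured
  ds1 <- makePatchDataset(classes, 8, seed = 3)
  mean_cyto <- tapply(seq_len(nPatches(ds1)), patchLabels(ds1), function(ii)
    mean(patchPixels(ds1)[, , 4, ii]))
  conf <- vapply(classes, function(p) p@channelIntensityMeans[4], 0)
  expect_equal(names(sort(mean_cyto)),
               names(sort(conf)))

  # byte-for-byte reproducibility through serialization
  td <- withr::local_tempdir()
  writePatchArchive(makePatchDataset(classes, 3, seed = 9),
                    file.path(td, "a"))
  writePatchArchive(makePatchDataset(classes, 3, seed = 9),
                    file.path(td, "b"))
  expect_identical(readBin(file.path(td, "a", "pixels.bin"), "raw", 1e7),
                   readBin(file.path(td, "b", "pixels.bin"), "raw", 1e7))
})

test_that("generated dead cells and doublets fail their rejection tests", {
  classes <- phantomClassPreset()
  set.seed(99)
  for (i in 1:50) {
    p <- classes[[(i %% length(classes)) + 1L]]
    dead <- sprite_candidate(p, seed = 1000 + i, dead = TRUE)
    expect_false(viabilityTest(dead))
  }
  for (i in 1:50) {
    p <- classes[[(i %% length(classes)) + 1L]]
    s1 <- renderCell(p, seed = 2000 + i)
    s2 <- renderCell(p, seed = 3000 + i)
    gap <- ceiling(s1$nucleusRadius + s2$nucleusRadius + 4)
    cand <- sprite_candidate(p, seed = 4000 + i, offset = c(-gap %/% 2, 0))
    def <- phenocyte:::.phantom_defaults
    cand$pixels <- round(pmin(phenocyte:::.paste_sprite(
      cand$pixels, s2$planes, 38 + gap - gap %/% 2, 38), 2^14 - 1))
    mt <- multiplicityTest(cand)
    expect_false(mt$pass)
  }
})

test_that("truth labeling matches segmented centroids to classes", {
  seg <- acceptance_segmentation()
  labeled <- assignTruthLabels(seg$patches, acceptance_scene())
  expect_equal(sum(!is.na(patchLabels(labeled))), nPatches(seg$patches))
})

test_that("separation scaling interpolates class parameters", {
  classes <- sep4_classes()
  collapsed <- scaleSeparation(classes, 0)
  r <- vapply(collapsed, function(p) p@nucleusRadius[1], 0)
  expect_true(all(abs(r - mean(r)) < 1e-12))
  same <- scaleSeparation(classes, 1)
  expect_equal(vapply(same, function(p) p@channelIntensityMeans[2], 0),
               vapply(classes, function(p) p@channelIntensityMeans[2], 0))
})

test_that("held-out accuracy rises with inter-class separation", {
  base <- sep4_classes()
  accs <- vapply(c(0.25, 0.6, 1.0), function(f) {
    classes <- scaleSeparation(base, f)
    ds <- makePatchDataset(classes, 60, seed = 77)
    plan <- kfoldSplit(ds, 4, seed = 1)
    hold <- which(foldAssignments(plan) == 1)
    m <- buildNetwork(networkSpec(4, widthScale = 1 / 8),
                      classNames = sort(unique(patchLabels(ds))), seed = 1)
    m <- trainNetwork(m, ds[-hold], epochs = 6, batchSize = 16, seed = 2,
                      valData = ds[hold])
    max(trainingHistory(m)$val_accuracy)  # best achieved on held-out
  }, 0)
  expect_true(all(diff(accs) >= -0.025))  # nondecreasing, ties at ceiling
  expect_gt(accs[3], accs[1])
})
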