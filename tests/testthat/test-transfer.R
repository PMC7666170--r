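test_that("freezing records a digest and splits parameter counts correctly", {
  m <- tiny_trained_model()
  fz <- freezeConv(m)
  expect_gt(length(fz@frozenLayers), 0)
  expect_match(fz@frozenDigest, "^[0-9a-f]{32}$")

  # trainable parameters = fully connected stage only (spec arithmetic)
  counts <- parameterCounts(fz)
  spec <- modelSpec(m)
  w <- scaledWidths(spec)
  flat <- attr(networkShapes(spec), "flattenLength")
  # each batch norm holds 2 parameter tensors (gamma, beta) of its width
  fc_expected <-
    (flat * w$fc[1] + w$fc[1]) + 2 * w$fc[1] +
    (w$fc[1] * w$fc[2] + w$fc[2]) + 2 * w$fc[2] +
    (w$fc[2] * w$fc[3] + w$fc[3]) + 2 * w$fc[3] +
    (w$fc[3] * spec@nClasses + spec@nClasses)
  expect_equal(unname(counts["trainable"]), fc_expected)

  conv_expected <- local({
    k <- spec@kernelSizes; cin <- spec@inputChannels; tot <- 0
    for (i in 1:4) {
      tot <- tot + k[i]^2 * cin * w$conv[i] + w$conv[i] + 2 * w$conv[i]
      cin <- w$conv[i]
    }
    tot
  })
  expect_equal(unname(counts["frozen"]), conv_expected)

  untrained <- buildNetwork(networkSpec(nClasses = 2, widthScale = 1 / 16),
                            seed = 1)
  expect_warning(freezeConv(untrained), "untrained")
})

test_that("head replacement resizes the output and keeps features bitwise", {
  m <- tiny_trained_model()
  ds <- small4_dataset()
  f_before <- extractFeatures(m, ds[1:3])
  m2 <- replaceHead(m, c("p", "q", "r"), seed = 9)
  expect_equal(classNames(m2), c("p", "q", "r"))
  probs <- predictProba(m2, ds[1:3])
  expect_equal(dim(probs), c(3L, 3L))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-9)
  expect_identical(extractFeatures(m2, ds[1:3]), f_before)
  expect_error(replaceHead(m, "only_one"), "at least 2")
})

test_that("frozen parameters survive transfer training bitwise", {
  base <- tiny_trained_model()
  # a 'different instrument': same four phenotypes re-imaged with shifted
  # optics emulated by re-scaled radii and intensities
  new_classes <- lapply(sep4_classes(), function(p) {
    PhantomClassParams(paste0(p@className, "_t"),
                       p@nucleusRadius * c(1.12, 1),
                       p@cytoplasmRadius * c(1.12, 1),
                       p@actinTextureScale,
                       p@channelIntensityMeans * 0.85,
                       p@eccentricity)
  })
  new_ds <- makePatchDataset(new_classes, 25, seed = 55)
  plan <- kfoldSplit(new_ds, 5, seed = 1)
  hold <- which(foldAssignments(plan) == 1)
  tm <- transferTrain(base, new_ds[-hold], epochs = 2, batchSize = 32,
                      seed = 7, valData = new_ds[hold])
  expect_identical(frozenDigest(tm), tm@frozenDigest)
  expect_equal(nrow(trainingHistory(tm)), 2L)
  expect_equal(length(classNames(tm)), 4L)
  # conv parameters match the base model exactly
  conv_ids <- tm@frozenLayers
  for (i in conv_ids)
    expect_identical(tm@layers[[i]]$W, base@layers[[i]]$W)
})

test_that("transfer on the base distribution recovers base-level accuracy", {
  ds <- makePatchDataset(phantomSeparablePreset(), 60, seed = 81)
  plan <- kfoldSplit(ds, 5, seed = 2)
  hold <- which(foldAssignments(plan) == 1)
  spec <- networkSpec(nClasses = 4, widthScale = 1 / 8)
  cls <- sort(unique(patchLabels(ds)))
  base <- buildNetwork(spec, classNames = cls, seed = 1)
  base <- trainNetwork(base, ds[-hold], epochs = 6, batchSize = 16,
                       seed = 2, valData = ds[hold])
  base_acc <- utils::tail(trainingHistory(base)$val_accuracy, 1)

  fresh <- makePatchDataset(phantomSeparablePreset(), 50, seed = 91)
  plan2 <- kfoldSplit(fresh, 5, seed = 1)
  h2 <- which(foldAssignments(plan2) == 1)
  tm <- transferTrain(base, fresh[-h2], epochs = 8, batchSize = 8,
                      seed = 3, valData = fresh[h2])
  t_acc <- max(trainingHistory(tm)$val_accuracy)
  expect_gte(t_acc, base_acc - 0.02)
})
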