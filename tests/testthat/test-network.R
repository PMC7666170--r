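test_that("architecture audit: layer sequence, kernels and widths", {
  spec <- networkSpec(nClasses = 8)
  m <- buildNetwork(spec, seed = 1)
  types <- vapply(m@layers, `[[`, "", "type")
  expect_equal(types, c(
    "conv", "bn_conv", "relu", "pool",
    "conv", "bn_conv", "relu", "pool",
    "conv", "bn_conv", "relu",
    "conv", "bn_conv", "relu", "pool",
    "flatten",
    "fc", "bn_fc", "relu", "dropout",
    "fc", "bn_fc", "relu", "dropout",
    "fc", "bn_fc", "relu", "dropout",
    "fc", "softmax"))
  convs <- m@layers[types == "conv"]
  expect_equal(vapply(convs, `[[`, 0L, "kh"), c(7L, 5L, 3L, 3L))
  expect_equal(vapply(convs, function(l) ncol(l$W), 0L),
               c(256L, 128L, 64L, 64L))
  fcs <- m@layers[types == "fc"]
  expect_equal(vapply(fcs, function(l) nrow(l$W), 0L),
               c(128L, 128L, 128L, 8L))
  expect_equal(vapply(m@layers[types == "dropout"], `[[`, 0, "rate"),
               rep(0.2, 3))
})

test_that("feature-map sizes follow the valid/pool-stride-2 arithmetic", {
  spec <- networkSpec(nClasses = 8, widthScale = 1 / 8)
  sh <- networkShapes(spec)
  expect_equal(sh$size, c(75L, 69L, 34L, 30L, 15L, 13L, 11L, 5L))
  # the flatten length scales with width but not with spatial arithmetic
  expect_equal(attr(networkShapes(networkSpec(8)), "flattenLength"), 1600L)
  # a built model's first fc layer matches the computed flatten length
  m <- buildNetwork(spec, seed = 1)
  first_fc <- which(vapply(m@layers, `[[`, "", "type") == "fc")[1]
  expect_equal(ncol(m@layers[[first_fc]]$W),
               attr(networkShapes(spec), "flattenLength"))
})

test_that("probabilities are softmax-normalized, batch-consistent, and uniform for a zeroed head", {
  ds <- small4_dataset()
  m <- buildNetwork(networkSpec(nClasses = 4, widthScale = 1 / 16),
                    classNames = sort(unique(patchLabels(ds))), seed = 3)
  x <- patchPixels(ds)[, , , c(1, 1, 5, 9), drop = FALSE]
  p <- predictProba(m, x)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-9)
  expect_equal(p[1, ], p[2, ])  # duplicated patch -> identical rows

  head_id <- max(which(vapply(m@layers, `[[`, "", "type") == "fc"))
  m@layers[[head_id]]$W[] <- 0
  m@layers[[head_id]]$b[] <- 0
  p0 <- predictProba(m, x)
  expect_equal(as.numeric(p0), rep(0.25, length(p0)))
})

test_that("single-channel variants accept one plane with the same trunk", {
  spec1 <- networkSpec(nClasses = 4, inputChannels = 1, widthScale = 1 / 16)
  m1 <- buildNetwork(spec1, seed = 2)
  expect_equal(nrow(m1@layers[[1]]$W), 7 * 7 * 1)
  ds <- channelSubset(small4_dataset(), "brightfield")
  p <- predictProba(m1, ds)
  expect_equal(dim(p), c(200L, 4L))
  # trunk shapes identical to the 4-channel variant
  sh4 <- networkShapes(networkSpec(nClasses = 4, widthScale = 1 / 16))
  expect_equal(networkShapes(spec1)$size, sh4$size)
})

test_that("rotation augmentation is a lossless group action preserving histograms", {
  px <- patchPixels(small4_dataset())[, , , 1]
  expect_identical(augmentRotate(px, 0), px)
  expect_identical(augmentRotate(px, 4), px)
  expect_identical(augmentRotate(augmentRotate(px, 1), 1),
                   augmentRotate(px, 2))
  r3 <- augmentRotate(px, 3)
  for (ch in 1:4)
    expect_identical(sort(as.numeric(r3[, , ch])),
                     sort(as.numeric(px[, , ch])))
})

test_that("balancing subsamples, passes through, and pads with true rotations", {
  expect_equal(nrow(balancePlan(c(a = 10000), 10000, 1)), 10000L)
  plan <- balancePlan(c(a = 10000), 10000, 1)
  expect_true(all(plan$rotation == 0L))
  expect_identical(plan$source, 1:10000)

  expect_error(balancePlan(c(a = 5, b = 0), 7), "empty class")

  ds <- small4_dataset()[1:103]  # classes of 50, 50, 3
  bal <- balanceClasses(ds, 7, seed = 2)
  expect_equal(as.integer(table(patchLabels(bal))), rep(7L, 3))
  # each padded item of the 3-item class matches an original under rotation
  small_class <- patchLabels(ds)[101]
  orig <- patchPixels(ds)[, , , 101:103, drop = FALSE]
  out_idx <- which(patchLabels(bal) == small_class)
  expect_equal(length(out_idx), 7L)
  for (i in out_idx) {
    candidate <- patchPixels(bal)[, , , i]
    match_found <- any(vapply(1:3, function(j) any(vapply(0:3, function(k)
      identical(augmentRotate(orig[, , , j], k), candidate), TRUE)), TRUE))
    expect_true(match_found)
  }
})

test_that("training records history, is seed-deterministic, and rejects label mismatches", {
  ds <- small4_dataset()[c(1:8, 51:58, 101:108, 151:158)]
  spec <- networkSpec(nClasses = 4, widthScale = 1 / 16)
  cls <- sort(unique(patchLabels(ds)))
  m0 <- buildNetwork(spec, classNames = cls, seed = 1)
  m1 <- trainNetwork(m0, ds, epochs = 1, batchSize = 32, seed = 5)
  expect_equal(nrow(trainingHistory(m1)), 1L)
  expect_true(all(is.finite(trainingHistory(m1)$loss)))

  m2 <- trainNetwork(m0, ds, epochs = 1, batchSize = 32, seed = 5)
  expect_identical(trainingHistory(m1)$accuracy,
                   trainingHistory(m2)$accuracy)
  expect_identical(m1@layers, m2@layers)

  bad <- buildNetwork(spec, classNames = c("w", "x", "y", "z"), seed = 1)
  expect_error(trainNetwork(bad, ds, epochs = 1), "contract violation")

  unb <- small4_dataset()[c(1:10, 51:53, 101:103, 151:153)]
  expect_warning(trainNetwork(m0, unb, epochs = 1, batchSize = 16, seed = 1),
                 "not balanced")
})

test_that("training reduces loss on separable phantoms and the oracle agrees", {
  ds <- small4_dataset()
  expect_gt(centroid_oracle_accuracy(ds), 0.9)
  m <- tiny_trained_model()
  h <- trainingHistory(m)
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_true(all(is.finite(h$loss)))
})

test_that("penultimate features are nonnegative, width-scaled and deterministic", {
  m <- tiny_trained_model()
  ds <- small4_dataset()
  f <- extractFeatures(m, ds[1:6])
  expect_equal(dim(f), c(6L, as.integer(round(128 / 16))))
  expect_gte(min(f), 0)
  f2 <- extractFeatures(m, ds[c(1, 1)])
  expect_identical(f2[1, ], f2[2, ])
})
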