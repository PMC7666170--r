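# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# four well-separated phantom classes used across tests
sep4_classes <- function() {
  phantomClassPreset()[c("lymphoid_a", "monocytic_a", "epithelial_large",
                         "large_round")]
}

# small labeled dataset (4 classes x 50) for unit tests
small4_dataset <- function() {
  fixture("small4", makePatchDataset(sep4_classes(), 50, seed = 42))
}

# the acceptance phantom scene (20 viable, 5 doublet, 5 dead, 3 border)
acceptance_scene <- function() {
  fixture("scene2055",
          makeScene(phantomClassPreset(),
                    c(viable_cell = 20, doublet = 5, dead_cell = 5,
                      border_cell = 3), seed = 11))
}

acceptance_segmentation <- function() {
  fixture("seg2055", segmentFrame(sceneFrame(acceptance_scene())))
}

# tiny trained model on the small dataset; reused by transfer tests
tiny_trained_model <- function() {
  fixture("tiny_model", {
    ds <- small4_dataset()
    spec <- networkSpec(nClasses = 4, widthScale = 1 / 16)
    m <- buildNetwork(spec, classNames = sort(unique(patchLabels(ds))),
                      seed = 1)
    trainNetwork(m, ds, epochs = 3, batchSize = 32, seed = 2)
  })
}

# nearest-centroid classifier on per-channel patch means: the independent
# separability oracle used to justify CNN accuracy thresholds
centroid_oracle_accuracy <- function(dataset) {
  labs <- patchLabels(dataset)
  px <- patchPixels(dataset)
  feat <- t(apply(px, 4, function(a) apply(a, 3, mean)))
  classes <- sort(unique(labs))
  pred <- vapply(seq_along(labs), function(i) {
    cent <- vapply(classes, function(cl)
      colMeans(feat[labs == cl & seq_along(labs) != i, , drop = FALSE]),
      numeric(ncol(feat)))
    classes[which.min(colSums((cent - feat[i, ])^2))]
  }, "")
  mean(pred == labs)
}

# render a raw-intensity candidate patch from a sprite (background + noise),
# bypassing scene placement; used by rejection-rule tests
sprite_candidate <- function(params, seed, dead = FALSE, offset = c(0, 0)) {
  def <- phenocyte:::.phantom_defaults
  if (dead) params@channelIntensityMeans[4] <- 0
  sp <- renderCell(params, seed)
  canvas <- array(rep(def$background, each = 75 * 75), c(75, 75, 4))
  canvas <- canvas + array(stats::rnorm(75 * 75 * 4, 0, def$noise_sd),
                           c(75, 75, 4))
  canvas <- phenocyte:::.paste_sprite(canvas, sp$planes, 38 + offset[1],
                                      38 + offset[2])
  px <- round(pmin(pmax(canvas, 0), 2^14 - 1))
  structure(list(pixels = px, centroid = c(row = 38, col = 38),
                 fieldId = "synthetic", bitDepth = 14L),
            class = "candidatePatch")
}
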