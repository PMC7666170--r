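#' @include AllClasses.R evaluation.R io.R phantom.R segmentation.R training.R
NULL

#' Evaluate a trained model on a labeled dataset
#'
#' Computes the full evaluation report: class-normalized confusion matrix,
#' per-class precision/recall/F1 with macro averages, one-vs-all ROC with
#' macro curve, cumulative probability curves on a 0.05 grid, overall
#' accuracy, and optionally a t-SNE embedding of the penultimate features.
#'
#' @param model a trained [TrainedModel-class].
#' @param dataset a labeled [PatchSet-class]; labels must be model classes.
#' @param tsne compute the t-SNE embedding of the penultimate features.
#' @param tsnePerplexity,tsneIterations,tsneSeed embedding settings.
#' @return list with `accuracy`, `confusion`, `metrics`, `roc`, `cumcurves`,
#'   `tsne` (NULL unless requested), `predicted`, `probs`.
#' @export
evaluateModel <- function(model, dataset, tsne = FALSE, tsnePerplexity = 30,
                          tsneIterations = 500L, tsneSeed = 1L) {
  truth <- patchLabels(dataset)
  if (anyNA(truth)) .stopf("dataset contains unlabeled patches")
  probs <- predictProba(model, dataset)
  predicted <- model@classNames[max.col(probs, ties.method = "first")]
  order <- model@classNames[model@classNames %in% unique(truth)]
  emb <- NULL
  if (tsne) {
    feats <- extractFeatures(model, dataset)
    emb <- tsneEmbed(feats, perplexity = tsnePerplexity,
                     iterations = tsneIterations, seed = tsneSeed)
    attr(emb, "group") <- truth
  }
  list(accuracy = mean(predicted == truth),
       confusion = confusionMatrix(truth, predicted, order),
       metrics = metricsTable(truth, predicted, order),
       roc = rocMacro(probs, truth),
       cumcurves = cumulativeProbCurves(probs, truth),
       tsne = emb, predicted = predicted, probs = probs)
}

#' Write an evaluation report to disk
#'
#' Serializes the report to `confusion.csv`, `metrics.csv` (rows = classes
#' plus AVERAGE), `roc_points.csv` (per-class and macro curves, long
#' format), `cumulative_curves.tsv`, optionally `tsne.csv`, and a
#' `report.json` with the headline numbers plus the seed/config digest that
#' produced them.
#'
#' @param report list from [evaluateModel()].
#' @param dir output directory.
#' @param meta optional named list (e.g. seed, config digest) stored in
#'   `report.json`.
#' @return invisibly, `dir`.
#' @export
writeEvaluationReport <- function(report, dir, meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(dir, "confusion.csv"))
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  roc_long <- do.call(rbind, c(
    lapply(names(report$roc$perClass), function(cl)
      data.frame(curve = cl, report$roc$perClass[[cl]])),
    list(data.frame(curve = "macro", report$roc$macro))))
  utils::write.csv(roc_long, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.table(report$cumcurves,
                     file.path(dir, "cumulative_curves.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$tsne)) {
    utils::write.csv(data.frame(group = attr(report$tsne, "group"),
                                x = report$tsne[, 1], y = report$tsne[, 2]),
                     file.path(dir, "tsne.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    c(list(accuracy = report$accuracy,
           macro_f1 = report$metrics$f1[nrow(report$metrics)],
           macro_auc = report$roc$macroAUC), meta),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pipeline configuration
#'
#' Validated settings for [runPipeline()].  Unknown keys are rejected, and
#' basic domain checks run before any computation.
#'
#' @param outDir output directory for all artifacts.
#' @param classes named list of [PhantomClassParams-class] (defaults to four
#'   well-separated classes of the built-in preset).
#' @param nFields number of phantom fields to render.
#' @param countsPerField named object counts per field (see [makeScene()]).
#' @param frameShape frame shape in px.
#' @param seed master seed for the whole run.
#' @param segmentation a [segmentationConfig()].
#' @param holdoutFrac fraction of labeled patches held out for testing.
#' @param balanceTarget patches per class after balancing (NULL disables).
#' @param channels channel names to train on ("all" or a subset like "bf").
#' @param widthScale,poolStride,padding network reductions (see
#'   [networkSpec()]).
#' @param epochs,lr,batchSize training hyperparameters.
#' @param tsne include a t-SNE embedding in the report.
#' @return validated config (named list, class "phenocyteConfig").
#' @export
pipelineConfig <- function(outDir, classes = NULL, nFields = 2L,
                           countsPerField = c(viable_cell = 12, doublet = 2,
                                              dead_cell = 2, border_cell = 2),
                           frameShape = c(1212L, 1212L), seed = 1L,
                           segmentation = segmentationConfig(),
                           holdoutFrac = 0.25, balanceTarget = NULL,
                           channels = "all", widthScale = 0.125,
                           poolStride = 2L, padding = "valid", epochs = 5L,
                           lr = 0.001, batchSize = 32L, tsne = FALSE) {
  if (is.null(classes)) {
    classes <- phantomClassPreset()[c("lymphoid_a", "monocytic_a",
                                      "epithelial_large", "large_round")]
  }
  stopifnot(holdoutFrac > 0, holdoutFrac < 1, epochs >= 1, lr > 0,
            nFields >= 1)
  cfg <- list(outDir = outDir, classes = classes, nFields = nFields,
              countsPerField = countsPerField, frameShape = frameShape,
              seed = as.integer(seed), segmentation = segmentation,
              holdoutFrac = holdoutFrac, balanceTarget = balanceTarget,
              channels = channels, widthScale = widthScale,
              poolStride = as.integer(poolStride), padding = padding,
              epochs = as.integer(epochs), lr = lr,
              batchSize = as.integer(batchSize), tsne = tsne)
  structure(cfg, class = "phenocyteConfig")
}

.config_digest <- function(config) {
  cfg <- unclass(config)
  cfg$classes <- lapply(cfg$classes, function(p)
    list(p@className, p@nucleusRadius, p@cytoplasmRadius, p@actinTextureScale,
         p@channelIntensityMeans, p@eccentricity))
  .param_digest(cfg)
}

#' Run the end-to-end phantom pipeline
#'
#' Chains the stages: render phantom scenes, write and re-read them as
#' per-channel TIFFs, segment every frame, label accepted patches from
#' ground truth, split train/test, optionally balance, train the classifier,
#' and evaluate — writing the patch archive, checkpoint, report files and a
#' structured log (per-field detection/acceptance/rejection counters and
#' per-class tallies) under `config$outDir`.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the trained model, the report, per-field
#'   counters and the artifact paths.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "phenocyteConfig"))
    .stopf("config must come from pipelineConfig()")
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  digest <- .config_digest(config)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("phenocyte pipeline | seed %d | config %s\n", config$seed,
              digest), file = log_path)

  # stage 1-2: phantom scenes -> TIFF -> segmentation
  sets <- list()
  counters <- list()
  for (f in seq_len(config$nFields)) {
    scene <- makeScene(config$classes, config$countsPerField,
                       frameShape = config$frameShape,
                       seed = config$seed + f,
                       fieldId = sprintf("field%02d", f))
    sdir <- file.path(out, "scenes")
    writeScene(scene, sdir)
    frame <- readWidefieldTiffs(sdir)[[sprintf("field%02d", f)]]
    seg <- segmentFrame(frame, config$segmentation)
    patches <- assignTruthLabels(seg$patches, scene)
    keep <- !is.na(patchLabels(patches))
    tally <- table(factor(seg$rejections$reason))
    counters[[f]] <- list(field = frame@fieldId,
                          detected = nPatches(seg$patches) +
                            nrow(seg$rejections),
                          accepted = nPatches(seg$patches),
                          rejected = as.list(tally))
    logf("field %s: detected=%d accepted=%d rejected={%s}", frame@fieldId,
         counters[[f]]$detected, counters[[f]]$accepted,
         paste(sprintf("%s:%d", names(tally), tally), collapse = ", "))
    utils::write.table(seg$rejections,
                       file.path(out, sprintf("%s_rejections.tsv",
                                              frame@fieldId)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    sets[[f]] <- patches[which(keep)]
  }
  patches <- combinePatchSets(sets)
  tab <- table(patchLabels(patches))
  logf("labeled patches per class: %s",
       paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  writePatchArchive(patches, file.path(out, "patches"), seed = config$seed)

  # stage 3: split, balance, channel subset
  labels <- patchLabels(patches)
  test_idx <- .with_seed(config$seed, {
    unlist(lapply(split(seq_along(labels), labels), function(ii)
      sample(ii, max(1, round(length(ii) * config$holdoutFrac)))),
      use.names = FALSE)
  })
  train_set <- patches[-test_idx]
  test_set <- patches[test_idx]
  if (!is.null(config$balanceTarget))
    train_set <- balanceClasses(train_set, config$balanceTarget,
                                seed = config$seed)
  if (!identical(config$channels, "all")) {
    idx <- match(config$channels, c("bf", "nuc", "actin", "cyto"))
    train_set <- channelSubset(train_set, idx)
    test_set <- channelSubset(test_set, idx)
  }

  # stage 4-5: train + evaluate
  classes <- sort(unique(patchLabels(train_set)))
  spec <- networkSpec(nClasses = length(classes),
                      inputChannels = dim(train_set@pixels)[3],
                      widthScale = config$widthScale,
                      poolStride = config$poolStride,
                      padding = config$padding)
  model <- buildNetwork(spec, classNames = classes, seed = config$seed)
  model <- trainNetwork(model, train_set, epochs = config$epochs,
                        lr = config$lr, batchSize = config$batchSize,
                        seed = config$seed, valData = test_set)
  saveModel(model, file.path(out, "checkpoint"),
            provenance = list(configDigest = digest, seed = config$seed))
  report <- evaluateModel(model, test_set, tsne = config$tsne,
                          tsneSeed = config$seed)
  writeEvaluationReport(report, file.path(out, "report"),
                        meta = list(seed = config$seed,
                                    configDigest = digest))
  logf("test accuracy %.3f | macro F1 %.3f", report$accuracy,
       report$metrics$f1[nrow(report$metrics)])
  invisible(list(model = model, report = report, counters = counters,
                 paths = list(archive = file.path(out, "patches"),
                              checkpoint = file.path(out, "checkpoint"),
                              report = file.path(out, "report"),
                              log = log_path)))
}
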