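#' @include AllClasses.R utils.R network.R
NULL

#' Stratified k-fold split
#'
#' Partitions a labeled dataset into k folds, stratified by class: folds are
#' disjoint, exhaustive, and per-class fold sizes differ by at most one.
#'
#' @param x a labeled [PatchSet-class] or a label vector.
#' @param k number of folds (default 5).
#' @param seed partition seed.
#' @return a [FoldPlan-class].
#' @export
kfoldSplit <- function(x, k = 5L, seed = 1L) {
  labels <- if (is(x, "PatchSet")) patchLabels(x) else as.character(x)
  if (anyNA(labels)) .stopf("cannot split unlabeled items")
  tab <- table(labels)
  if (any(tab < k))
    .stopf("class '%s' has %d items, fewer than k = %d",
           names(tab)[which.min(tab)], min(tab), k)
  assignments <- integer(length(labels))
  .with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  new("FoldPlan", k = as.integer(k), assignments = assignments,
      seed = as.integer(seed))
}

#' Exhaustive k-fold cross-validation
#'
#' Trains k models, each on k-1 folds, evaluating the held-out fold at the
#' end of every epoch; reports per-epoch mean and standard deviation of
#' validation accuracy across folds.
#'
#' @param dataset a labeled [PatchSet-class].
#' @param spec a [NetworkSpec-class] matching the dataset's channels.
#' @param k number of folds.
#' @param epochs,lr,batchSize training hyperparameters (see
#'   [trainNetwork()]).
#' @param seed seed driving the fold plan, initialization and training.
#' @param verbose print progress.
#' @return list with `history` (data.frame epoch, mean_accuracy,
#'   sd_accuracy), `perFold` (k x epochs matrix), `plan` (the
#'   [FoldPlan-class]), `finalMean`, `finalSd`.
#' @export
crossValidate <- function(dataset, spec, k = 5L, epochs = 25L, lr = 0.001,
                          batchSize = 64L, seed = 1L, verbose = FALSE) {
  plan <- kfoldSplit(dataset, k, seed)
  classes <- sort(unique(patchLabels(dataset)))
  if (spec@nClasses != length(classes))
    .stopf("spec declares %d classes but the dataset has %d",
           spec@nClasses, length(classes))
  per_fold <- matrix(NA_real_, k, epochs)
  for (f in seq_len(k)) {
    hold <- which(plan@assignments == f)
    model <- buildNetwork(spec, classNames = classes, seed = seed + f)
    model <- trainNetwork(model, dataset[-hold], epochs = epochs, lr = lr,
                          batchSize = batchSize, seed = seed + 1000L * f,
                          valData = dataset[hold])
    per_fold[f, ] <- trainingHistory(model)$val_accuracy
    if (verbose)
      message(sprintf("fold %d/%d: final val accuracy %.3f", f, k,
                      per_fold[f, epochs]))
  }
  history <- data.frame(epoch = seq_len(epochs),
                        mean_accuracy = colMeans(per_fold),
                        sd_accuracy = apply(per_fold, 2, stats::sd))
  list(history = history, perFold = per_fold, plan = plan,
       finalMean = history$mean_accuracy[epochs],
       finalSd = history$sd_accuracy[epochs])
}

#' Class-normalized confusion matrix
#'
#' Entry (i, j) is the fraction of class-i items predicted as class j; each
#' row sums to 1 and the diagonal is the per-class recall.
#'
#' @param trueLabels,predictedLabels character vectors.
#' @param classOrder optional class ordering; every class must appear in
#'   `trueLabels`.
#' @return nClasses x nClasses numeric matrix.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, classOrder = NULL) {
  if (is.null(classOrder)) classOrder <- sort(unique(trueLabels))
  if (!all(trueLabels %in% classOrder) || !all(predictedLabels %in% classOrder))
    .stopf("labels outside the declared class order")
  if (!all(classOrder %in% trueLabels))
    .stopf("class '%s' absent from trueLabels",
           setdiff(classOrder, trueLabels)[1])
  tt <- table(factor(trueLabels, classOrder),
              factor(predictedLabels, classOrder))
  m <- unclass(tt / rowSums(tt))
  attr(m, "dimnames") <- list(true = classOrder, predicted = classOrder)
  m
}

#' Unweighted (macro) average
#' @param values numeric vector of per-class metric values.
#' @return their unweighted mean.
#' @export
macroAverage <- function(values) mean(values)

#' Per-class precision, recall and F1 with macro averages
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean; the
#' AVERAGE row is the unweighted mean over classes.  Zero-division (a class
#' never predicted, or an F1 with zero precision+recall) yields 0 with a
#' warning.
#'
#' @param trueLabels,predictedLabels character vectors.
#' @param classOrder optional class ordering.
#' @return data.frame with columns class, precision, recall, f1; one row per
#'   class plus a final "AVERAGE" row.
#' @export
metricsTable <- function(trueLabels, predictedLabels, classOrder = NULL) {
  if (is.null(classOrder)) classOrder <- sort(unique(trueLabels))
  tt <- table(factor(trueLabels, classOrder),
              factor(predictedLabels, classOrder))
  tp <- diag(tt)
  fp <- colSums(tt) - tp
  fn <- rowSums(tt) - tp
  zdiv <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning(sprintf("%s undefined for class(es) %s; reported as 0", what,
                      paste(classOrder[den == 0], collapse = ", ")),
              call. = FALSE)
    out
  }
  precision <- zdiv(tp, tp + fp, "precision")
  recall <- zdiv(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  out <- data.frame(class = classOrder, precision = as.numeric(precision),
                    recall = as.numeric(recall), f1 = as.numeric(f1),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(class = "AVERAGE",
                        precision = macroAverage(out$precision),
                        recall = macroAverage(out$recall),
                        f1 = macroAverage(out$f1)))
}

#' Cumulative probability curves per (true, predicted) class pair
#'
#' For every pair (true class t, class c), the cumulative frequency of the
#' predicted probability of c among items of t, evaluated on a fixed
#' probability grid.  For a predictive pair the curve stays near 0 until
#' probabilities close to 1 (mass skewed toward 1); for an unpredictive pair
#' it jumps to 1 immediately.
#'
#' @param probs N x nClasses probability matrix (rows sum to 1) with class
#'   name columns.
#' @param trueLabels character vector of length N.
#' @param bin probability bin width (default 0.05).
#' @return long data.frame with columns true, predicted, p (grid value),
#'   cumfreq; each curve is nondecreasing and ends at 1.
#' @export
cumulativeProbCurves <- function(probs, trueLabels, bin = 0.05) {
  if (max(abs(rowSums(probs) - 1)) > 1e-6)
    .stopf("probability rows must sum to 1")
  classes <- colnames(probs)
  grid <- seq(0, 1, by = bin)
  out <- list()
  for (t in unique(trueLabels)) {
    sel <- trueLabels == t
    for (c in classes) {
      pc <- probs[sel, c]
      out[[length(out) + 1L]] <- data.frame(
        true = t, predicted = c, p = grid,
        cumfreq = vapply(grid, function(e) mean(pc <= e), 0),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' One-vs-all ROC curves with macro average
#'
#' Each class's curve treats that class as positive and all others as one
#' negative group, thresholding the class's probability column.  Per-class
#' curves are interpolated onto a common false-positive-rate grid and
#' averaged pointwise; the macro AUC is the unweighted mean of per-class
#' AUCs.
#'
#' @param probs N x nClasses probability matrix with class name columns.
#' @param trueLabels character vector of length N.
#' @param gridSize number of FPR grid points for the macro curve.
#' @return list with `perClass` (named list of data.frame(fpr, tpr)), `auc`
#'   (named per-class AUC), `macro` (data.frame(fpr, tpr)), `macroAUC`.
#' @export
rocMacro <- function(probs, trueLabels, gridSize = 1001L) {
  classes <- colnames(probs)
  if (length(classes) < 2L) .stopf("need at least 2 classes")
  if (max(abs(rowSums(probs) - 1)) > 1e-6)
    .stopf("probability rows must sum to 1")
  grid <- seq(0, 1, length.out = gridSize)
  per_class <- list()
  aucs <- numeric(0)
  tpr_grid <- matrix(NA_real_, gridSize, length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    resp <- factor(trueLabels == cl, levels = c(FALSE, TRUE))
    r <- pROC::roc(response = resp, predictor = probs[, cl],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    fpr <- rev(1 - r$specificities)
    tpr <- rev(r$sensitivities)
    per_class[[cl]] <- data.frame(fpr = fpr, tpr = tpr)
    aucs[cl] <- as.numeric(pROC::auc(r))
    # collapse vertical segments (duplicate fpr) to their top, then linear
    tops <- tapply(tpr, fpr, max)
    xs <- as.numeric(names(tops))
    tpr_grid[, i] <- stats::approx(xs, as.numeric(tops), xout = grid,
                                   rule = 2, ties = "ordered")$y
  }
  list(perClass = per_class, auc = aucs,
       macro = data.frame(fpr = grid, tpr = rowMeans(tpr_grid)),
       macroAUC = as.numeric(macroAverage(aucs)))
}

#' Query a held-out ("unseen") class against a model of the others
#'
#' Trains a classifier on every class except `heldOutClass` (output layer
#' sized nClasses - 1), classifies the held-out items against the trained
#' classes, and reports their probability matrix and cumulative probability
#' curves; optionally a joint t-SNE of held-out plus trained-class features.
#'
#' @param dataset a labeled [PatchSet-class] with at least 3 classes.
#' @param heldOutClass the class to withhold from training.
#' @param widthScale,poolStride architecture reduction (see [networkSpec()]).
#' @param epochs,lr,batchSize training hyperparameters.
#' @param seed seed.
#' @param tsne compute the joint embedding (slower).
#' @param tsnePerplexity,tsneIterations embedding settings when `tsne` is
#'   TRUE.
#' @return list with `model`, `probs` (held-out items x trained classes),
#'   `curves` (cumulative probability curves of the held-out items), and
#'   `tsne` (coordinates with a `group` attribute, or NULL).
#' @export
unseenClassQuery <- function(dataset, heldOutClass, widthScale = 1,
                             poolStride = 2L, epochs = 25L, lr = 0.001,
                             batchSize = 64L, seed = 1L, tsne = FALSE,
                             tsnePerplexity = 30, tsneIterations = 500L) {
  labels <- patchLabels(dataset)
  classes <- sort(unique(labels))
  if (length(classes) < 3L) .stopf("need at least 3 classes in the dataset")
  if (!heldOutClass %in% classes)
    .stopf("held-out class '%s' not present", heldOutClass)
  trained_classes <- setdiff(classes, heldOutClass)
  hold <- which(labels == heldOutClass)
  train_set <- dataset[-hold]
  spec <- networkSpec(nClasses = length(trained_classes),
                      inputChannels = dim(dataset@pixels)[3],
                      widthScale = widthScale, poolStride = poolStride)
  model <- buildNetwork(spec, classNames = trained_classes, seed = seed)
  model <- trainNetwork(model, train_set, epochs = epochs, lr = lr,
                        batchSize = batchSize, seed = seed)
  held_set <- dataset[hold]
  probs <- predictProba(model, held_set)
  curves <- cumulativeProbCurves(probs,
                                 rep(heldOutClass, nrow(probs)))
  emb <- NULL
  if (tsne) {
    feats <- rbind(extractFeatures(model, held_set),
                   extractFeatures(model, train_set))
    emb <- tsneEmbed(feats, perplexity = tsnePerplexity,
                     iterations = tsneIterations, seed = seed)
    attr(emb, "group") <- c(rep(heldOutClass, length(hold)),
                            patchLabels(train_set))
  }
  list(model = model, probs = probs, curves = curves, tsne = emb)
}
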