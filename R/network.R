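#' @include AllClasses.R utils.R
NULL

#' Construct a network architecture descriptor
#'
#' Defaults describe the reference patch classifier: four convolution blocks
#' of widths (256, 128, 64, 64), kernels (7, 5, 3, 3), stride 1, each with
#' batch normalization and ReLU; 2 x 2 max-pooling after blocks 1, 2 and 4;
#' three 128-node fully connected blocks with batch normalization, ReLU and
#' 20% dropout; and a softmax output.  `widthScale` shrinks all widths
#' proportionally for desk-scale experiments.
#'
#' @param nClasses number of output classes (>= 2).
#' @param inputChannels 4 for the full four-channel model, 1 for
#'   single-channel variants.
#' @param widthScale width multiplier in (0, 1].
#' @param poolStride max-pooling stride: 2 (conventional, default) or 1
#'   (literal near-full-size pooling; supported and audited, but it makes the
#'   flatten layer enormous).
#' @param padding convolution padding, "valid" (default) or "same".
#' @param inputSize spatial input size (75).
#' @param convWidths,kernelSizes,fcWidths,poolSize,dropoutRate architecture
#'   constants; override only for experiments.
#' @return a [NetworkSpec-class].
#' @export
networkSpec <- function(nClasses, inputChannels = 4L, widthScale = 1,
                        poolStride = 2L, padding = c("valid", "same"),
                        inputSize = 75L, convWidths = c(256L, 128L, 64L, 64L),
                        kernelSizes = c(7L, 5L, 3L, 3L),
                        fcWidths = c(128L, 128L, 128L), poolSize = 2L,
                        dropoutRate = 0.2) {
  new("NetworkSpec", inputChannels = as.integer(inputChannels),
      inputSize = as.integer(inputSize), nClasses = as.integer(nClasses),
      convWidths = as.integer(convWidths),
      kernelSizes = as.integer(kernelSizes), fcWidths = as.integer(fcWidths),
      poolSize = as.integer(poolSize), poolStride = as.integer(poolStride),
      dropoutRate = dropoutRate, padding = match.arg(padding),
      widthScale = widthScale)
}

#' Widths of a spec after width scaling
#' @param spec a [NetworkSpec-class].
#' @return list with `conv` and `fc` integer widths.
#' @export
scaledWidths <- function(spec) {
  list(conv = pmax(1L, as.integer(round(spec@convWidths * spec@widthScale))),
       fc = pmax(1L, as.integer(round(spec@fcWidths * spec@widthScale))))
}

#' Feature-map shape audit of an architecture
#'
#' Walks the layer sequence computing spatial sizes and channel counts; the
#' flatten length is the product of the last convolution-stage shape.
#'
#' @param spec a [NetworkSpec-class].
#' @return data.frame with columns stage, size, channels; the flatten length
#'   is in attribute "flattenLength".
#' @export
networkShapes <- function(spec) {
  w <- scaledWidths(spec)$conv
  k <- spec@kernelSizes
  s <- spec@inputSize
  ch <- spec@inputChannels
  pad <- function(kk) if (spec@padding == "same") (kk - 1L) %/% 2L else 0L
  rows <- list(data.frame(stage = "input", size = s, channels = ch))
  conv <- function(i) {
    s <<- s + 2L * pad(k[i]) - k[i] + 1L
    ch <<- w[i]
    rows[[length(rows) + 1L]] <<- data.frame(stage = paste0("conv", i),
                                             size = s, channels = ch)
  }
  pool <- function() {
    s <<- (s - spec@poolSize) %/% spec@poolStride + 1L
    rows[[length(rows) + 1L]] <<- data.frame(stage = "pool", size = s,
                                             channels = ch)
  }
  conv(1); pool(); conv(2); pool(); conv(3); conv(4); pool()
  out <- do.call(rbind, rows)
  attr(out, "flattenLength") <- s * s * ch
  out
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# He-uniform initialization
.he_unif <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

#' Build an untrained model
#'
#' Instantiates all layer parameters of the architecture with seeded
#' variance-scaling uniform initialization.
#'
#' @param spec a [NetworkSpec-class].
#' @param classNames ordered class names (length `nClasses`); defaults to
#'   class1..classK.
#' @param seed initialization seed.
#' @return an untrained [TrainedModel-class].
#' @export
buildNetwork <- function(spec, classNames = NULL, seed = 1L) {
  validObject(spec)
  if (is.null(classNames))
    classNames <- paste0("class", seq_len(spec@nClasses))
  if (length(classNames) != spec@nClasses)
    .stopf("classNames must have length nClasses = %d", spec@nClasses)
  w <- scaledWidths(spec)
  k <- spec@kernelSizes
  pad <- function(kk) if (spec@padding == "same") (kk - 1L) %/% 2L else 0L
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  .with_seed(seed, {
    inC <- spec@inputChannels
    conv_block <- function(i) {
      K <- k[i] * k[i] * inC
      add(list(type = "conv", id = length(layers) + 1L,
               W = matrix(.he_unif(K * w$conv[i], K), K, w$conv[i]),
               b = numeric(w$conv[i]),
               kh = k[i], kw = k[i], pad = pad(k[i]), stage = "conv"))
      add(list(type = "bn_conv", C = w$conv[i], gamma = rep(1, w$conv[i]),
               beta = numeric(w$conv[i]), rmean = numeric(w$conv[i]),
               rvar = rep(1, w$conv[i]), stage = "conv"))
      add(list(type = "relu", stage = "conv"))
      inC <<- w$conv[i]
    }
    pool_layer <- function()
      add(list(type = "pool", size = spec@poolSize,
               stride = spec@poolStride, stage = "conv"))
    conv_block(1); pool_layer()
    conv_block(2); pool_layer()
    conv_block(3); conv_block(4); pool_layer()
    add(list(type = "flatten", stage = "conv"))
    flat <- attr(networkShapes(spec), "flattenLength")
    inF <- flat
    for (j in 1:3) {
      add(list(type = "fc",
               W = matrix(.he_unif(w$fc[j] * inF, inF), w$fc[j], inF),
               b = numeric(w$fc[j]), stage = "fc"))
      add(list(type = "bn_fc", C = w$fc[j], gamma = rep(1, w$fc[j]),
               beta = numeric(w$fc[j]), rmean = numeric(w$fc[j]),
               rvar = rep(1, w$fc[j]), stage = "fc"))
      add(list(type = "relu", stage = "fc",
               feature = (j == 3L)))  # penultimate feature tap
      add(list(type = "dropout", rate = spec@dropoutRate, stage = "fc"))
      inF <- w$fc[j]
    }
    add(list(type = "fc",
             W = matrix(.he_unif(spec@nClasses * inF, inF),
                        spec@nClasses, inF),
             b = numeric(spec@nClasses), stage = "head"))
    add(list(type = "softmax", stage = "head"))
  })
  new("TrainedModel", spec = spec, layers = layers,
      history = data.frame(), classNames = as.character(classNames),
      frozenLayers = integer(0), frozenDigest = "", seed = as.integer(seed))
}

.param_names <- function(l)
  switch(l$type, conv = , fc = c("W", "b"),
         bn_conv = , bn_fc = c("gamma", "beta"), character(0))

.is_frozen <- function(model, i) i %in% model@frozenLayers

# ---- forward ---------------------------------------------------------------

# x: (H, W, C, N) array.  Returns list(out = nClasses x N probabilities,
# caches, layers (running stats possibly updated), features).
.forward <- function(layers, x, training = FALSE, frozen = integer(0),
                     capture_features = FALSE) {
  caches <- vector("list", length(layers))
  features <- NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    use_batch <- training && !(i %in% frozen)
    switch(l$type,
      conv = {
        caches[[i]] <- list(x = x, dims = dim(x))
        x <- .conv_forward(x, dim(x), l$W, l$b, l$kh, l$kw, l$pad)
      },
      bn_conv = {
        if (use_batch) {
          st <- .bn_conv_stats(x, dim(x))
          layers[[i]]$rmean <- (1 - .bn_momentum) * l$rmean +
            .bn_momentum * st$mean
          layers[[i]]$rvar <- (1 - .bn_momentum) * l$rvar +
            .bn_momentum * st$var
          caches[[i]] <- list(x = x, dims = dim(x), mean = st$mean,
                              var = st$var)
          x <- .bn_conv_apply(x, dim(x), l$gamma, l$beta, st$mean, st$var,
                              .bn_eps)
        } else {
          x <- .bn_conv_apply(x, dim(x), l$gamma, l$beta, l$rmean, l$rvar,
                              .bn_eps)
        }
      },
      relu = {
        x <- pmax(x, 0)
        caches[[i]] <- list(y = x)
        if (capture_features && isTRUE(l$feature)) features <- x
      },
      pool = {
        r <- .maxpool_forward(x, dim(x), l$size, l$stride)
        caches[[i]] <- list(idx = r$idx, dims = dim(x))
        x <- r$y
      },
      flatten = {
        caches[[i]] <- list(dims = dim(x))
        x <- matrix(x, prod(dim(x)[1:3]), dim(x)[4])
      },
      fc = {
        caches[[i]] <- list(x = x)
        x <- l$W %*% x + l$b
      },
      bn_fc = {
        if (use_batch) {
          m <- rowMeans(x)
          v <- pmax(rowMeans(x * x) - m * m, 0)
          layers[[i]]$rmean <- (1 - .bn_momentum) * l$rmean + .bn_momentum * m
          layers[[i]]$rvar <- (1 - .bn_momentum) * l$rvar + .bn_momentum * v
          caches[[i]] <- list(x = x, mean = m, var = v)
          x <- (x - m) / sqrt(v + .bn_eps) * l$gamma + l$beta
        } else {
          x <- (x - l$rmean) / sqrt(l$rvar + .bn_eps) * l$gamma + l$beta
        }
      },
      dropout = {
        if (training && l$rate > 0) {
          mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
          dim(mask) <- dim(x)
          caches[[i]] <- list(mask = mask)
          x <- x * mask
        }
      },
      softmax = {
        z <- x - rep(apply(x, 2, max), each = nrow(x))
        e <- exp(z)
        x <- e / rep(colSums(e), each = nrow(x))
      },
      .stopf("unknown layer type '%s'", l$type))
  }
  list(out = x, caches = caches, layers = layers, features = features)
}

# ---- backward --------------------------------------------------------------

# d: gradient wrt the pre-softmax logits (nClasses x N).  Computes parameter
# gradients for trainable layers and propagates dx down to the lowest
# trainable layer.  Returns list of per-layer gradient lists.
.backward <- function(layers, caches, d, trainable) {
  grads <- vector("list", length(layers))
  stop_at <- min(trainable)
  for (i in seq(length(layers) - 1L, 1L)) {  # skip the softmax layer
    l <- layers[[i]]
    want_grad <- i %in% trainable
    switch(l$type,
      fc = {
        if (want_grad)
          grads[[i]] <- list(W = d %*% t(caches[[i]]$x), b = rowSums(d))
        if (i == stop_at) break
        d <- t(l$W) %*% d
      },
      bn_fc = {
        cc <- caches[[i]]
        inv <- 1 / sqrt(cc$var + .bn_eps)
        xhat <- (cc$x - cc$mean) * inv
        dgamma <- rowSums(d * xhat)
        dbeta <- rowSums(d)
        if (want_grad) grads[[i]] <- list(gamma = dgamma, beta = dbeta)
        if (i == stop_at) break
        d <- (l$gamma * inv) * (d - (dbeta + xhat * dgamma) / ncol(cc$x))
      },
      relu = { d <- d * (caches[[i]]$y > 0) },
      dropout = { if (!is.null(caches[[i]])) d <- d * caches[[i]]$mask },
      flatten = {
        if (i <= stop_at) break
        d <- array(d, caches[[i]]$dims)
      },
      pool = {
        if (i <= stop_at) break
        d <- .maxpool_backward(caches[[i]]$idx, d, caches[[i]]$dims)
      },
      conv = {
        if (want_grad || i > stop_at) {
          r <- .conv_backward(caches[[i]]$x, caches[[i]]$dims, l$W, d,
                              l$kh, l$kw, l$pad, need_dx = i > stop_at)
          if (want_grad) grads[[i]] <- list(W = r$dW, b = r$db)
          if (i == stop_at) break
          d <- r$dx
        }
      },
      bn_conv = {
        cc <- caches[[i]]
        r <- .bn_conv_backward(cc$x, cc$dims, l$gamma, cc$mean, cc$var, d,
                               .bn_eps)
        if (want_grad) grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
        if (i == stop_at) break
        d <- r$dx
      },
      softmax = NULL)
    if (i <= stop_at && !is.null(grads[[i]])) break
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(layers, trainable) {
  lapply(seq_along(layers), function(i) {
    if (!(i %in% trainable)) return(NULL)
    pn <- .param_names(layers[[i]])
    if (!length(pn)) return(NULL)
    st <- lapply(pn, function(p) {
      v <- layers[[i]][[p]]
      list(m = v * 0, v = v * 0)
    })
    names(st) <- pn
    st
  })
}

.adam_step <- function(layers, grads, state, t, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]]) || is.null(state[[i]])) next
    for (p in names(state[[i]])) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

# ---- training --------------------------------------------------------------

.one_hot <- function(labels, classNames) {
  idx <- match(labels, classNames)
  if (anyNA(idx))
    .stopf("contract violation: dataset labels not in model class names: %s",
           paste(unique(labels[is.na(idx)]), collapse = ", "))
  Y <- matrix(0, length(classNames), length(labels))
  Y[cbind(idx, seq_along(labels))] <- 1
  Y
}

.trainable_layers <- function(model)
  setdiff(which(vapply(model@layers,
                       function(l) length(.param_names(l)) > 0, TRUE)),
          model@frozenLayers)

# inference forward in batches; returns nClasses x N probability matrix
.infer <- function(model, px, batchSize = 256L, capture_features = FALSE) {
  n <- dim(px)[4]
  out <- NULL
  feats <- NULL
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    fw <- .forward(model@layers, px[, , , idx, drop = FALSE],
                   training = FALSE, capture_features = capture_features)
    out <- cbind(out, fw$out)
    if (capture_features) feats <- cbind(feats, fw$features)
  }
  list(probs = out, features = feats)
}

.check_channels <- function(model, px) {
  if (dim(px)[3] != model@spec@inputChannels)
    .stopf("patch channel count (%d) does not match the model input (%d)",
           dim(px)[3], model@spec@inputChannels)
}

#' Train a patch classifier
#'
#' Minimizes softmax cross-entropy with Adam.  Per-epoch training loss and
#' accuracy are recorded; when `valData` is given, held-out accuracy is
#' evaluated at the end of every epoch.  Deterministic for a fixed seed and
#' thread policy.
#'
#' @param model a [TrainedModel-class] (untrained or resumed).
#' @param dataset a labeled [PatchSet-class]; labels must be a subset of
#'   `classNames(model)`.  A warning is emitted when class counts are
#'   unbalanced.
#' @param epochs number of epochs (reference setting: 25).
#' @param lr Adam learning rate (reference setting: 0.001).
#' @param batchSize minibatch size.
#' @param seed seed for shuffling, dropout and (implicitly) batch order.
#' @param valData optional labeled [PatchSet-class] for per-epoch validation.
#' @param verbose print one line per epoch.
#' @return the trained [TrainedModel-class] with filled history.
#' @export
trainNetwork <- function(model, dataset, epochs = 25L, lr = 0.001,
                         batchSize = 64L, seed = 1L, valData = NULL,
                         verbose = FALSE) {
  px <- patchPixels(dataset)
  .check_channels(model, px)
  labels <- patchLabels(dataset)
  if (anyNA(labels)) .stopf("dataset contains unlabeled patches")
  tab <- table(labels)
  if (length(unique(tab)) > 1L)
    warning("training dataset is not balanced: counts ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
            call. = FALSE)
  Y <- .one_hot(labels, model@classNames)
  n <- dim(px)[4]
  layers <- model@layers
  trainable <- .trainable_layers(model)
  state <- .adam_init(layers, trainable)
  t_step <- 0L
  history <- model@history
  frozen <- model@frozenLayers
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq(1L, n, by = batchSize)) {
        idx <- perm[start:min(n, start + batchSize - 1L)]
        xb <- px[, , , idx, drop = FALSE]
        yb <- Y[, idx, drop = FALSE]
        fw <- .forward(layers, xb, training = TRUE, frozen = frozen)
        layers <- fw$layers
        p <- fw$out
        loss <- -mean(colSums(yb * log(pmax(p, 1e-12))))
        if (!is.finite(loss)) .stopf("non-finite training loss at epoch %d", ep)
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(t(p), ties.method = "first") ==
                max.col(t(yb), ties.method = "first"))
        d <- (p - yb) / length(idx)
        grads <- .backward(layers, fw$caches, d, trainable)
        t_step <- t_step + 1L
        upd <- .adam_step(layers, grads, state, t_step, lr)
        layers <- upd$layers
        state <- upd$state
      }
      row <- data.frame(epoch = nrow(history) + 1L, loss = ep_loss / n,
                        accuracy = ep_correct / n,
                        val_accuracy = NA_real_)
      if (!is.null(valData)) {
        tmp <- model
        tmp@layers <- layers
        row$val_accuracy <- .accuracy(tmp, valData)
      }
      history <- rbind(history, row)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f%s", row$epoch, row$loss,
                        row$accuracy,
                        if (is.na(row$val_accuracy)) "" else
                          sprintf(" val %.3f", row$val_accuracy)))
    }
  })
  model@layers <- layers
  model@history <- history
  model
}

.accuracy <- function(model, dataset) {
  p <- predictProba(model, dataset)
  pred <- model@classNames[max.col(p, ties.method = "first")]
  mean(pred == patchLabels(dataset))
}

#' Class probabilities for patches
#'
#' Runs the model in inference mode (dropout off, batch normalization using
#' running statistics).  Rows sum to 1.
#'
#' @param model a [TrainedModel-class].
#' @param patches a [PatchSet-class] or (H, W, C, N) array.
#' @param batchSize inference batch size.
#' @return N x nClasses probability matrix with class name columns.
#' @export
predictProba <- function(model, patches, batchSize = 256L) {
  px <- if (is(patches, "PatchSet")) patchPixels(patches) else patches
  .check_channels(model, px)
  p <- t(.infer(model, px, batchSize)$probs)
  colnames(p) <- model@classNames
  p
}

#' Penultimate-layer feature vectors
#'
#' Returns the post-ReLU activation of the last fully connected feature block
#' (128 nodes at full width; scales with `widthScale`), the representation
#' used for t-SNE clustering.
#'
#' @param model a [TrainedModel-class].
#' @param patches a [PatchSet-class] or (H, W, C, N) array.
#' @param batchSize inference batch size.
#' @return N x featureWidth matrix (entries >= 0).
#' @export
extractFeatures <- function(model, patches, batchSize = 256L) {
  px <- if (is(patches, "PatchSet")) patchPixels(patches) else patches
  .check_channels(model, px)
  t(.infer(model, px, batchSize, capture_features = TRUE)$features)
}

#' Predicted class labels
#' @param model a [TrainedModel-class].
#' @param patches a [PatchSet-class] or array.
#' @return character vector of predicted class names.
#' @export
predictClasses <- function(model, patches) {
  p <- predictProba(model, patches)
  model@classNames[max.col(p, ties.method = "first")]
}
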