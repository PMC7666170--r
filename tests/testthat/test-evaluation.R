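test_that("k-fold splits partition with per-class balance and seeded determinism", {
  labels <- rep(c("a", "b"), each = 10)
  plan <- kfoldSplit(labels, 5, seed = 3)
  a <- foldAssignments(plan)
  expect_equal(length(a), 20L)
  expect_equal(sort(unique(a)), 1:5)
  for (f in 1:5)
    expect_equal(as.integer(table(labels[a == f])), c(2L, 2L))

  plan2 <- kfoldSplit(labels, 5, seed = 3)
  expect_identical(foldAssignments(plan2), a)
  plan3 <- kfoldSplit(labels, 5, seed = 4)
  expect_false(identical(foldAssignments(plan3), a))

  big <- kfoldSplit(rep("x", 100), 5, seed = 1)
  expect_equal(as.integer(table(foldAssignments(big))), rep(20L, 5))
  expect_error(kfoldSplit(rep(c("a", "b"), c(10, 3)), 5), "fewer than k")
})

test_that("confusion matrices are class-normalized with recall on the diagonal", {
  t1 <- rep(c("a", "b"), each = 10)
  expect_equal(confusionMatrix(t1, t1), diag(2),
               ignore_attr = TRUE)
  p <- c(rep("a", 8), "b", "b", rep("b", 10))
  cm <- confusionMatrix(t1, p)
  expect_equal(unname(cm["a", ]), c(0.8, 0.2))
  expect_equal(rowSums(cm), c(a = 1, b = 1))
  const <- confusionMatrix(t1, rep("a", 20))
  expect_equal(unname(const[, "a"]), c(1, 1))

  mt <- suppressWarnings(metricsTable(t1, p))
  expect_equal(mt$recall[mt$class != "AVERAGE"], diag(cm),
               ignore_attr = TRUE)
})

test_that("metric arithmetic handles perfection, zero-division and macro rows", {
  t1 <- rep(c("a", "b", "c"), each = 4)
  mt <- metricsTable(t1, t1)
  expect_true(all(mt[, c("precision", "recall", "f1")] == 1))

  never_c <- ifelse(t1 == "c", "a", t1)
  expect_warning(mt2 <- metricsTable(t1, never_c), "precision")
  expect_equal(mt2$precision[mt2$class == "c"], 0)
  expect_equal(mt2$f1[mt2$class == "c"], 0)
  avg <- mt2[mt2$class == "AVERAGE", ]
  expect_equal(avg$f1, macroAverage(mt2$f1[mt2$class != "AVERAGE"]))
})

test_that("cumulative probability curves are monotone CDFs on the 0.05 grid", {
  n <- 40
  probs <- cbind(a = rep(1, n), b = rep(0, n))
  cc <- cumulativeProbCurves(probs, rep("a", n))
  a_curve <- cc$cumfreq[cc$predicted == "a"]
  expect_equal(a_curve, c(rep(0, 20), 1))  # all mass at p = 1
  b_curve <- cc$cumfreq[cc$predicted == "b"]
  expect_equal(b_curve, rep(1, 21))        # all mass at p = 0
  expect_equal(cc$p[cc$predicted == "a"], seq(0, 1, 0.05))

  set.seed(9)
  u <- runif(10000)
  cu <- cumulativeProbCurves(cbind(a = u, b = 1 - u), rep("a", 10000))
  ua <- cu[cu$predicted == "a", ]
  expect_lt(max(abs(ua$cumfreq - ua$p)), 0.02)
  # monotone nondecreasing, ending at 1
  for (curve in split(cu, cu$predicted)) {
    expect_true(all(diff(curve$cumfreq) >= 0))
    expect_equal(curve$cumfreq[nrow(curve)], 1)
  }
  expect_error(cumulativeProbCurves(cbind(a = u, b = u), rep("a", 10000)),
               "sum to 1")
})

test_that("one-vs-all ROC: perfect separation, chance level, and averaging identity", {
  set.seed(12)
  n <- 10000
  t1 <- sample(c("a", "b", "c"), n, replace = TRUE)
  perfect <- matrix(0, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  perfect[cbind(seq_len(n), match(t1, c("a", "b", "c")))] <- 1
  rp <- rocMacro(perfect, t1)
  expect_equal(unname(rp$auc), rep(1, 3))
  expect_equal(rp$macroAUC, 1)

  rand <- matrix(runif(n * 3), n, 3)
  rand <- rand / rowSums(rand)
  colnames(rand) <- c("a", "b", "c")
  rr <- rocMacro(rand, t1)
  expect_lt(abs(rr$macroAUC - 0.5), 0.02)

  # two identical per-class curves average to themselves
  t2 <- rep(c("a", "b"), each = 50)
  s <- c(seq(0, 1, length.out = 50), seq(0, 1, length.out = 50))
  p2 <- cbind(a = s, b = 1 - s)
  r2 <- rocMacro(p2, t2)
  grid_tpr <- function(cl) {
    d <- r2$perClass[[cl]]
    tops <- tapply(d$tpr, d$fpr, max)
    stats::approx(as.numeric(names(tops)), as.numeric(tops),
                  xout = r2$macro$fpr, rule = 2)$y
  }
  expect_equal(r2$macro$tpr, (grid_tpr("a") + grid_tpr("b")) / 2)

  # AUC cross-check against a hand-rolled rank statistic (Mann-Whitney)
  pos <- rand[t1 == "a", "a"]; neg <- rand[t1 != "a", "a"]
  u <- (sum(rank(c(pos, neg))[seq_along(pos)]) -
          length(pos) * (length(pos) + 1) / 2) /
    (as.numeric(length(pos)) * length(neg))
  expect_equal(unname(rr$auc["a"]), u, tolerance = 1e-10)
})

test_that("macro AUC is invariant to class relabeling", {
  set.seed(13)
  n <- 600
  t1 <- sample(c("a", "b", "c"), n, replace = TRUE)
  p <- matrix(runif(n * 3) + 0.5 * (outer(t1, c("a", "b", "c"), "==")), n, 3)
  p <- p / rowSums(p)
  colnames(p) <- c("a", "b", "c")
  r1 <- rocMacro(p, t1)
  relabel <- c(a = "b", b = "c", c = "a")
  p2 <- p[, c("c", "a", "b")]
  colnames(p2) <- c("a", "b", "c")
  r2 <- rocMacro(p2, unname(relabel[t1]))
  expect_equal(r1$macroAUC, r2$macroAUC, tolerance = 1e-12)
})

test_that("t-SNE preserves well-separated clusters and honors its precondition", {
  set.seed(1)
  centers <- matrix(rnorm(4 * 16, sd = 6), 4, 16)
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(40 * 16, sd = 0.5), 40, 16), 2, centers[k, ], "+")))
  labels <- rep(1:4, each = 40)
  Y <- tsneEmbed(X, perplexity = 20, iterations = 600, seed = 3)
  expect_equal(dim(Y), c(160L, 2L))
  sil <- cluster::silhouette(labels, dist(Y))
  expect_gte(mean(sil[, 3]), 0.5)

  expect_identical(tsneEmbed(X, perplexity = 20, iterations = 100, seed = 3),
                   tsneEmbed(X, perplexity = 20, iterations = 100, seed = 3))
  expect_error(tsneEmbed(X[1:50, ], perplexity = 20), "perplexity")
})

test_that("cross-validation reports per-epoch mean and sd and never leaks folds", {
  ds <- small4_dataset()[c(1:12, 51:62, 101:112, 151:162)]
  spec <- networkSpec(nClasses = 4, widthScale = 1 / 16)
  cv <- crossValidate(ds, spec, k = 2, epochs = 2, batchSize = 16, seed = 5)
  expect_equal(dim(cv$perFold), c(2L, 2L))
  expect_equal(nrow(cv$history), 2L)
  expect_true(all(is.finite(cv$history$mean_accuracy)))
  expect_equal(cv$finalMean, cv$history$mean_accuracy[2])

  # fold audit: assignments partition the items; no item validates twice
  a <- foldAssignments(cv$plan)
  expect_equal(length(a), nPatches(ds))
  expect_equal(sort(unique(a)), 1:2)
  per_class <- table(patchLabels(ds), a)
  expect_true(all(abs(per_class[, 1] - per_class[, 2]) <= 1))
})

test_that("an unseen class concentrates probability on its trained twin", {
  classes <- phantomClassPreset()[c("lymphoid_a", "epithelial_large",
                                    "large_round")]
  twin <- phantomClassPreset()$lymphoid_b  # near-duplicate of lymphoid_a
  twin@className <- "unseen_lymphoid"
  ds <- combinePatchSets(makePatchDataset(classes, 60, seed = 31),
                         makePatchDataset(list(twin), 40, seed = 32))
  res <- unseenClassQuery(ds, "unseen_lymphoid", widthScale = 1 / 8,
                          epochs = 6, batchSize = 16, seed = 6)
  expect_equal(ncol(res$probs), 3L)  # output layer sized n_classes - 1
  expect_setequal(colnames(res$probs),
                  c("lymphoid_a", "epithelial_large", "large_round"))
  expect_gte(stats::median(res$probs[, "lymphoid_a"]), 0.5)
  # cumulative curves cover each trained class on the 0.05 grid
  expect_setequal(unique(res$curves$predicted), colnames(res$probs))
  expect_error(unseenClassQuery(ds, "absent"), "not present")
})
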