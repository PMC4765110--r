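## A cheap labeled feature table mimicking featurizeClusters() output:
## two informative dimensions separate H from NH.
fakeFeatures <- function(n, seed = 1L, sep = 4) {
  set.seed(seed)
  prov <- sample(c("H_SYNTH", "NH_RANDOM", "NH_EVOLVED_0",
                   "NH_EVOLVED_25", "NH_EVOLVED_50"), n, replace = TRUE)
  isH <- prov == "H_SYNTH"
  data.frame(
    clusterId = sprintf("c%04d", seq_len(n)),
    label = ifelse(isH, "H", "NH"),
    provenance = prov,
    aliscore = rnorm(n, ifelse(isH, 2, 2 + sep)),
    n_gaps = rnorm(n, ifelse(isH, 1, 1 + sep)),
    length = rnorm(n, 50, 5),
    stringsAsFactors = FALSE)
}

test_that("EQUAL and PROP compositions are honored exactly", {
  feats <- fakeFeatures(4000, seed = 2)
  eq <- assembleDataset(feats, "EQUAL", 500, seed = 3)
  expect_equal(nrow(eq), 500L)
  expect_equal(unname(table(eq$provenance)[c("H_SYNTH", "NH_RANDOM",
                                             "NH_EVOLVED_0", "NH_EVOLVED_25",
                                             "NH_EVOLVED_50")]),
               rep(100L, 5), ignore_attr = TRUE)
  pr <- assembleDataset(feats, "PROP", 400, seed = 3)
  expect_equal(sum(pr$label == "H"), 200L)
  expect_equal(unname(table(pr$provenance)[c("NH_RANDOM", "NH_EVOLVED_0",
                                             "NH_EVOLVED_25",
                                             "NH_EVOLVED_50")]),
               rep(50L, 4), ignore_attr = TRUE)
  expect_equal(nrow(assembleDataset(feats, "EQUAL", 0)), 0L)
  expect_error(assembleDataset(feats[1:20, ], "EQUAL", 500, seed = 1),
               "shortfall")
})

test_that("the 80/10/10 split partitions with remainder to train", {
  big <- fakeFeatures(11000, seed = 4)
  sp <- splitDataset(big, seed = 5)
  expect_equal(vapply(sp, nrow, 0L),
               c(train = 8800L, valid = 1100L, test = 1100L))
  small <- fakeFeatures(10, seed = 6)
  sp2 <- splitDataset(small, seed = 7)
  expect_equal(vapply(sp2, nrow, 0L),
               c(train = 8L, valid = 1L, test = 1L))
  # disjoint and exhaustive
  ids <- c(sp$train$clusterId, sp$valid$clusterId, sp$test$clusterId)
  expect_setequal(ids, big$clusterId)
  expect_equal(anyDuplicated(ids), 0L)
  expect_error(splitDataset(big, 0.7, 0.1, 0.1), "sum to 1")
})

test_that("all seven classifier kinds fit and predict deterministically", {
  feats <- fakeFeatures(160, seed = 8)
  sp <- splitDataset(feats, seed = 9)
  for (kind in c("mlp", "svm", "random_forest", "naive_bayes", "logistic",
                 "stack_with_lr", "stack_without_lr")) {
    m1 <- trainClassifier(kind, sp$train, seed = 10)
    m2 <- trainClassifier(kind, sp$train, seed = 10)
    expect_equal(predict(m1, sp$valid), predict(m2, sp$valid),
                 info = kind)
    acc <- evaluateClassifier(m1, sp$valid)$accuracy
    expect_gte(acc, 0.8)
  }
})

test_that("a separable table is learned perfectly by random forest", {
  tbl <- separableTable(60, seed = 11)
  m <- trainClassifier("random_forest", tbl, seed = 12)
  expect_equal(evaluateClassifier(m, tbl)$accuracy, 1.0)
})

test_that("single-class training data is rejected", {
  tbl <- separableTable(20, seed = 13)
  expect_error(trainClassifier("logistic", tbl[tbl$label == "H", ],
                               seed = 1), "single class")
})

test_that("prediction enforces the fitted feature schema", {
  tbl <- separableTable(30, seed = 14)
  m <- trainClassifier("logistic", tbl, seed = 15)
  expect_error(predict(m, tbl[, "f1", drop = FALSE]), "f2")
})

test_that("evaluation reports consistent confusion counts", {
  tbl <- separableTable(40, seed = 16)
  m <- trainClassifier("random_forest", tbl, seed = 17)
  rep <- evaluateClassifier(m, tbl)
  expect_equal(sum(rep$confusion), nrow(tbl))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  # a constant (intercept-only) predictor on a balanced table scores 0.5
  const <- data.frame(label = rep(c("H", "NH"), c(14, 6)), f1 = 1)
  mC <- trainClassifier("logistic", const, seed = 18)
  balanced <- data.frame(label = rep(c("H", "NH"), each = 10), f1 = 1)
  expect_equal(evaluateClassifier(mC, balanced)$accuracy, 0.5)
})

test_that("stacking over one base keeps close to that base's accuracy", {
  deficits <- vapply(1:8, function(s) {
    feats <- fakeFeatures(150, seed = 100 + s, sep = 2.2)
    sp <- splitDataset(feats, seed = 200 + s)
    base <- trainClassifier("naive_bayes", sp$train, seed = s)
    stack <- trainClassifier("stack_with_lr", sp$train, seed = s,
                             hyper = list(bases = "naive_bayes"))
    evaluateClassifier(base, sp$valid)$accuracy -
      evaluateClassifier(stack, sp$valid)$accuracy
  }, 0)
  expect_lte(mean(deficits), 0.02)
})

test_that("the learning curve degenerates to plain train-and-evaluate", {
  feats <- fakeFeatures(120, seed = 19)
  sp <- splitDataset(feats, seed = 20)
  cur <- learningCurve("random_forest", sp$train, sp$valid,
                       fractions = 1, nBootstrap = 1, seed = 21)
  m <- trainClassifier("random_forest", sp$train,
                       seed = deriveSeed(21, "fit_1_1"))
  expect_equal(cur$mean_accuracy,
               evaluateClassifier(m, sp$valid)$accuracy)
  expect_equal(cur$sd_accuracy, 0)
})

test_that("more training data does not hurt the learning curve", {
  feats <- fakeFeatures(200, seed = 22, sep = 2.5)
  sp <- splitDataset(feats, seed = 23)
  cur <- learningCurve("random_forest", sp$train, sp$valid,
                       fractions = c(0.05, 1), nBootstrap = 10, seed = 24)
  expect_gte(cur$mean_accuracy[2],
             cur$mean_accuracy[1] - (cur$upper[1] - cur$lower[1]))
})

test_that("feature ablation scores each feature individually", {
  feats <- fakeFeatures(150, seed = 25)
  feats$noise <- 1  # constant, uninformative feature
  sp <- splitDataset(feats, seed = 26)
  ab <- featureAblation("logistic", sp$train, sp$valid, seed = 27)
  expect_equal(nrow(ab), 4L)
  expect_setequal(ab$feature, c("aliscore", "n_gaps", "length", "noise"))
  full <- evaluateClassifier(
    trainClassifier("logistic", sp$train, seed = 27), sp$valid)$accuracy
  expect_true(all(ab$accuracy <= full + 0.1))
  majority <- max(table(labels <- sp$valid$label)) / nrow(sp$valid)
  expect_lt(abs(ab$accuracy[ab$feature == "noise"] - majority), 0.15)
})

test_that("filtering conserves the cluster set and quarantines failures", {
  hs <- makeHSynthetic(4, sizeLambda = 4, rootLengthRange = c(40L, 60L),
                       seed = 28)
  nh <- lapply(1:4, function(i)
    makeNHEvolved(hs[[i]], wagModel(0), treeParams(), seed = 30 + i))
  feats <- featurizeClusters(c(hs, nh),
                             rparams = randomnessParams(seed = 31))
  m <- trainClassifier("random_forest", feats, seed = 32)
  out <- filterClusters(m, c(hs, nh), rparams = randomnessParams(seed = 31))
  expect_equal(length(out$kept) + length(out$removed), 8L)
  expect_equal(nrow(out$manifest), 8L)
  expect_setequal(out$manifest$decision, c("kept", "removed"))
})

test_that("classifiers persist through a file round-trip", {
  tbl <- separableTable(30, seed = 33)
  m <- trainClassifier("logistic", tbl, seed = 34)
  tf <- withr::local_tempfile(fileext = ".rds")
  saveClassifier(m, tf)
  m2 <- loadClassifier(tf)
  expect_equal(predict(m, tbl), predict(m2, tbl))
})
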