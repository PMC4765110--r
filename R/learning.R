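## learning: dataset assembly, splitting, the classifier zoo (five base
## learners + two stacking meta-classifiers), evaluation, learning curves,
## single-feature ablation, and cluster filtering.

#' Assemble an EQUAL- or PROP-composition labeled dataset
#'
#' EQUAL: the five provenance classes (homology, random-draw, and the
#' three evolved non-homology types at 0/25/50 percent invariable sites)
#' in equal counts. PROP: half homology, the other half split equally
#' among the four non-homology types.
#'
#' @param features feature table from [featurizeClusters()] (columns
#'   \code{clusterId}, \code{label}, \code{provenance} + features).
#' @param scheme \code{"EQUAL"} or \code{"PROP"}.
#' @param nTotal total rows requested (divisible by 5 for EQUAL, by 8 for
#'   PROP; 0 returns an empty table).
#' @param seed integer seed for the per-class subsampling.
#' @return Subset of \code{features} with the requested composition.
#' @examples
#' \dontrun{assembleDataset(tbl, "EQUAL", 500, seed = 1)}
#' @export
assembleDataset <- function(features, scheme = c("EQUAL", "PROP"), nTotal,
                            seed = NA_integer_) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(features), nTotal >= 0)
  if (nTotal == 0L) return(features[0L, , drop = FALSE])
  nhTypes <- c("NH_RANDOM", "NH_EVOLVED_0", "NH_EVOLVED_25", "NH_EVOLVED_50")
  if (scheme == "EQUAL") {
    if (nTotal %% 5 != 0)
      stop("EQUAL composition needs nTotal divisible by 5")
    want <- stats::setNames(rep(nTotal / 5, 5), c("H", nhTypes))
  } else {
    if (nTotal %% 8 != 0)
      stop("PROP composition needs nTotal divisible by 8")
    want <- stats::setNames(c(nTotal / 2, rep(nTotal / 8, 4)),
                            c("H", nhTypes))
  }
  poolIdx <- c(list(H = which(features$label == "H")),
               lapply(stats::setNames(nhTypes, nhTypes),
                      function(p) which(features$provenance == p)))
  short <- vapply(names(want),
                  function(k) want[[k]] - length(poolIdx[[k]]), 0)
  if (any(short > 0))
    stop("insufficient pool for composition; shortfall: ",
         paste(sprintf("%s needs %d more", names(want)[short > 0],
                       short[short > 0]), collapse = "; "))
  withLocalSeed(seed, {
    take <- unlist(lapply(names(want), function(k)
      poolIdx[[k]][sample.int(length(poolIdx[[k]]), want[[k]])]))
    out <- features[take, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Split a dataset into train/validation/test
#'
#' Random, unstratified sampling; validation and test sizes are the
#' rounded fractions and the remainder goes to training, so 11,000 rows at
#' 0.8/0.1/0.1 give 8,800/1,100/1,100.
#'
#' @param data data.frame with >= 10 rows.
#' @param trainFrac,validFrac,testFrac fractions summing to 1.
#' @param seed integer seed.
#' @return List with data.frames \code{train}, \code{valid}, \code{test}
#'   forming a disjoint, exhaustive partition of \code{data}.
#' @export
splitDataset <- function(data, trainFrac = 0.8, validFrac = 0.1,
                         testFrac = 0.1, seed = NA_integer_) {
  if (abs(trainFrac + validFrac + testFrac - 1) > 1e-8)
    stop("split fractions must sum to 1")
  n <- nrow(data)
  stopifnot(n >= 10L)
  nValid <- round(validFrac * n)
  nTest <- round(testFrac * n)
  withLocalSeed(seed, {
    idx <- sample.int(n)
    list(train = data[idx[seq_len(n - nValid - nTest)], , drop = FALSE],
         valid = data[idx[n - nValid - nTest + seq_len(nValid)], , drop = FALSE],
         test  = data[idx[n - nTest + seq_len(nTest)], , drop = FALSE])
  })
}

featureSchema <- function(data) {
  setdiff(names(data), c("clusterId", "label", "provenance"))
}

## label factor with P(H) as the modeled probability
labelFactor <- function(x) factor(ifelse(x == "H", "H", "NH"),
                                  levels = c("NH", "H"))

scaleBySchema <- function(data, schema, center, scale) {
  X <- as.matrix(data[, schema, drop = FALSE])
  storage.mode(X) <- "double"
  sweep(sweep(X, 2L, center), 2L, scale, "/")
}

## ---- base learners -------------------------------------------------------
## Hyperparameters follow the study's reported settings mapped to their
## nearest portable equivalents: MLP with one hidden layer of
## (features+classes)/2 units and 3000 epochs (500 inside a stack),
## linear-polynomial SVM with C = 1, random forest with 10 trees, Gaussian
## naive Bayes, ridge-free logistic regression.

fitBase <- function(kind, X, y, seed, inStack = FALSE) {
  set.seed(deriveSeed(seed, paste0("base_", kind, if (inStack) "_st")))
  model <- switch(kind,
    mlp = nnet::nnet(X, ifelse(y == "H", 1, 0),
                     size = max(2L, round((ncol(X) + 2) / 2)),
                     entropy = TRUE, decay = 1e-4,
                     maxit = if (inStack) 500L else 3000L,
                     trace = FALSE, MaxNWts = 5000L),
    svm = e1071::svm(X, y, kernel = "polynomial", degree = 1L, gamma = 1,
                     coef0 = 0, cost = 1, probability = TRUE,
                     scale = FALSE),
    random_forest = randomForest::randomForest(
      as.data.frame(X), y, ntree = 10L),
    naive_bayes = e1071::naiveBayes(as.data.frame(X), y),
    logistic = suppressWarnings(
      stats::glm.fit(cbind(1, X), ifelse(y == "H", 1, 0),
                     family = stats::binomial())),
    stop("unknown base classifier kind: ", kind))
  list(kind = kind, model = model)
}

predictBase <- function(fit, X) {
  ## make sure the fitting package's S3 predict methods are registered,
  ## e.g. when a persisted model is deserialized into a fresh session
  requireNamespace(switch(fit$kind, mlp = "nnet",
                          svm = , naive_bayes = "e1071",
                          random_forest = "randomForest", "stats"),
                   quietly = TRUE)
  switch(fit$kind,
    mlp = as.numeric(stats::predict(fit$model, X)),
    svm = {
      pr <- attr(stats::predict(fit$model, X, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "H"])
    },
    random_forest = as.numeric(
      stats::predict(fit$model, as.data.frame(X), type = "prob")[, "H"]),
    naive_bayes = as.numeric(
      stats::predict(fit$model, as.data.frame(X), type = "raw")[, "H"]),
    logistic = {
      eta <- as.numeric(cbind(1, X) %*% ifelse(is.na(fit$model$coefficients),
                                               0, fit$model$coefficients))
      1 / (1 + exp(-eta))
    })
}

STACK_BASES <- list(
  stack_with_lr = c("logistic", "mlp", "random_forest", "naive_bayes", "svm"),
  stack_without_lr = c("mlp", "random_forest", "naive_bayes", "svm"))

## stratified k-fold assignment
foldIds <- function(y, k) {
  out <- integer(length(y))
  for (lv in levels(y)) {
    at <- which(y == lv)
    out[at] <- sample(rep_len(seq_len(k), length(at)))
  }
  out
}

#' Train a homology classifier
#'
#' Base kinds fit a single learner. Stacking kinds fit the base set, form
#' out-of-fold predicted class probabilities (10-fold, so the meta-learner
#' never sees resubstitution predictions), and fit a small feed-forward
#' network on them; at prediction time the bases (refitted on all training
#' rows) feed the meta-network. Deterministic given \code{seed}.
#'
#' @param kind one of \code{"mlp"}, \code{"svm"}, \code{"random_forest"},
#'   \code{"naive_bayes"}, \code{"logistic"}, \code{"stack_with_lr"},
#'   \code{"stack_without_lr"}.
#' @param data data.frame with a \code{label} column (\code{"H"} /
#'   \code{"NH"}) and feature columns; any \code{clusterId} /
#'   \code{provenance} columns are ignored.
#' @param seed integer seed.
#' @param hyper optional list: \code{bases} (character vector overriding a
#'   stack's base set), \code{folds} (out-of-fold count, default 10),
#'   \code{threshold} (P(H) decision cutoff, default 0.5).
#' @return A fitted [HomologyClassifier-class].
#' @seealso [evaluateClassifier()], [filterClusters()]
#' @export
trainClassifier <- function(kind, data, seed = 1L, hyper = list()) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  stopifnot(is.data.frame(data), "label" %in% names(data))
  schema <- featureSchema(data)
  if (!length(schema)) stop("no feature columns in training data")
  y <- labelFactor(data$label)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; need both H and NH")
  Xr <- as.matrix(data[, schema, drop = FALSE])
  storage.mode(Xr) <- "double"
  center <- colMeans(Xr)
  scl <- apply(Xr, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  X <- sweep(sweep(Xr, 2L, center), 2L, scl, "/")
  threshold <- if (!is.null(hyper$threshold)) hyper$threshold else 0.5

  if (!kind %in% names(STACK_BASES)) {
    fit <- fitBase(kind, X, y, seed)
    return(methods::new("HomologyClassifier", kind = kind, fit = fit,
                        baseFits = list(), meta = NULL,
                        baseKinds = character(), schema = schema,
                        center = center, scale = scl,
                        threshold = threshold, seed = as.numeric(seed)))
  }

  baseKinds <- if (!is.null(hyper$bases)) hyper$bases
               else STACK_BASES[[kind]]
  stopifnot(all(baseKinds %in% setdiff(CLASSIFIER_KINDS,
                                       names(STACK_BASES))))
  k <- if (!is.null(hyper$folds)) hyper$folds else 10L
  k <- min(k, min(table(y)))
  set.seed(deriveSeed(seed, "stack_folds"))
  fold <- foldIds(y, k)
  oof <- matrix(NA_real_, nrow(X), length(baseKinds),
                dimnames = list(NULL, baseKinds))
  for (f in seq_len(k)) {
    hold <- fold == f
    for (b in baseKinds) {
      bf <- fitBase(b, X[!hold, , drop = FALSE], y[!hold],
                    deriveSeed(seed, paste0("fold", f)), inStack = TRUE)
      oof[hold, b] <- predictBase(bf, X[hold, , drop = FALSE])
    }
  }
  baseFits <- lapply(stats::setNames(baseKinds, baseKinds),
                     function(b) fitBase(b, X, y, seed, inStack = TRUE))
  set.seed(deriveSeed(seed, "stack_meta"))
  meta <- nnet::nnet(oof, ifelse(y == "H", 1, 0),
                     size = max(2L, round((length(baseKinds) + 2) / 2)),
                     entropy = TRUE, decay = 1e-4, maxit = 500L,
                     trace = FALSE)
  methods::new("HomologyClassifier", kind = kind, fit = NULL,
               baseFits = baseFits, meta = meta, baseKinds = baseKinds,
               schema = schema, center = center, scale = scl,
               threshold = threshold, seed = as.numeric(seed))
}

#' Predict homology for featurized clusters
#'
#' @param object a fitted [HomologyClassifier-class].
#' @param newdata data.frame containing the model's feature schema
#'   (missing features raise an error listing them).
#' @param type \code{"prob"} for P(H), \code{"class"} for hard labels.
#' @return Numeric vector of P(H), or a factor with levels
#'   \code{NH}/\code{H}.
#' @export
setMethod("predict", "HomologyClassifier",
          function(object, newdata, type = c("prob", "class")) {
  type <- match.arg(type)
  missing <- setdiff(object@schema, names(newdata))
  if (length(missing))
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  X <- scaleBySchema(newdata, object@schema, object@center, object@scale)
  probH <- if (object@kind %in% names(STACK_BASES)) {
    basePr <- vapply(object@baseFits, function(bf) predictBase(bf, X),
                     numeric(nrow(X)))
    basePr <- matrix(basePr, nrow = nrow(X),
                     dimnames = list(NULL, object@baseKinds))
    requireNamespace("nnet", quietly = TRUE)
    as.numeric(stats::predict(object@meta, basePr))
  } else {
    predictBase(object@fit, X)
  }
  if (type == "prob") probH
  else factor(ifelse(probH >= object@threshold, "H", "NH"),
              levels = c("NH", "H"))
})

#' Evaluate a classifier on a labeled table
#'
#' @param model a fitted [HomologyClassifier-class].
#' @param data labeled feature table.
#' @return List of class \code{EvaluationReport}: \code{accuracy},
#'   \code{confusion} (2 x 2 truth-by-prediction counts), and
#'   \code{perClass} precision/recall.
#' @export
evaluateClassifier <- function(model, data) {
  stopifnot("label" %in% names(data))
  truth <- labelFactor(data$label)
  pred <- predict(model, data, type = "class")
  confusion <- table(truth = truth, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  perClass <- t(vapply(levels(truth), function(lv) {
    tp <- confusion[lv, lv]
    c(precision = if (sum(confusion[, lv]) > 0)
        tp / sum(confusion[, lv]) else NA_real_,
      recall = if (sum(confusion[lv, ]) > 0)
        tp / sum(confusion[lv, ]) else NA_real_)
  }, numeric(2L)))
  structure(list(accuracy = acc, confusion = confusion,
                 perClass = perClass, n = nrow(data)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport: accuracy ", sprintf("%.4f", x$accuracy),
      " on ", x$n, " instances\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Bootstrapped learning curve
#'
#' For each training fraction, resamples that share of the training rows
#' (without replacement) \code{nBootstrap} times, refits, and records
#' validation accuracy; reports the mean and an error envelope. A fraction
#' of 1 with one replicate reduces to a plain train-and-evaluate.
#'
#' @param kind classifier kind (see [trainClassifier()]).
#' @param train,valid labeled feature tables.
#' @param fractions vector of training-set fractions in (0, 1].
#' @param nBootstrap replicates per fraction (default 100).
#' @param seed integer seed.
#' @param hyper passed to [trainClassifier()].
#' @return data.frame with columns \code{fraction}, \code{n_train},
#'   \code{mean_accuracy}, \code{sd_accuracy}, \code{lower}, \code{upper}
#'   (2.5/97.5 percent envelope).
#' @export
learningCurve <- function(kind, train, valid,
                          fractions = c(0.01, 0.05, 0.1, 0.25, 0.5, 1),
                          nBootstrap = 100L, seed = 1L, hyper = list()) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  n <- nrow(train)
  y <- labelFactor(train$label)
  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    size <- max(2L, round(f * n))
    accs <- vapply(seq_len(nBootstrap), function(b) {
      sub <- if (size >= n) train else withLocalSeed(
        deriveSeed(seed, sprintf("curve_%d_%d", fi, b)), {
          repeat {
            idx <- sample.int(n, size)
            if (length(unique(y[idx])) == 2L) break
          }
          train[idx, , drop = FALSE]
        })
      m <- trainClassifier(kind, sub,
                           seed = deriveSeed(seed, sprintf("fit_%d_%d", fi, b)),
                           hyper = hyper)
      evaluateClassifier(m, valid)$accuracy
    }, 0)
    data.frame(fraction = f, n_train = size,
               mean_accuracy = mean(accs),
               sd_accuracy = if (length(accs) > 1) stats::sd(accs) else 0,
               lower = stats::quantile(accs, 0.025, names = FALSE),
               upper = stats::quantile(accs, 0.975, names = FALSE))
  })
  do.call(rbind, rows)
}

#' Single-feature ablation
#'
#' Trains one model per feature on that feature alone and reports
#' validation accuracy, ranking features by individual predictive value.
#'
#' @inheritParams learningCurve
#' @return data.frame with columns \code{feature}, \code{accuracy}.
#' @export
featureAblation <- function(kind, train, valid, seed = 1L, hyper = list()) {
  schema <- featureSchema(train)
  stopifnot(length(schema) >= 1L)
  acc <- vapply(schema, function(f) {
    m <- trainClassifier(kind, train[, c("label", f), drop = FALSE],
                         seed = deriveSeed(seed, paste0("ablate_", f)),
                         hyper = hyper)
    evaluateClassifier(m, valid[, c("label", f), drop = FALSE])$accuracy
  }, 0)
  data.frame(feature = schema, accuracy = unname(acc))
}

#' Filter a cluster set with a trained classifier
#'
#' Featurizes each cluster (aligning when needed), predicts, and splits
#' the input into kept (predicted H) and removed (predicted NH). Clusters
#' that cannot be featurized are quarantined with the error message, never
#' silently dropped.
#'
#' @param model a fitted [HomologyClassifier-class].
#' @param clusters list of [HomologyCluster-class] objects.
#' @param scheme an [aminoClassScheme()].
#' @param rparams a [randomnessParams()].
#' @param alnParams an [alignParams()].
#' @return List with \code{kept}, \code{removed} (cluster lists),
#'   \code{quarantined} (named character of error messages) and
#'   \code{manifest} (data.frame: clusterId, probH, decision).
#' @export
filterClusters <- function(model, clusters, scheme = aminoClassScheme(),
                           rparams = randomnessParams(seed = 1),
                           alnParams = alignParams()) {
  stopifnot(methods::is(model, "HomologyClassifier"), is.list(clusters))
  quarantined <- character()
  featRows <- list()
  ok <- logical(length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    row <- tryCatch(featurizeClusters(list(cl), scheme, rparams, alnParams),
                    error = function(e) conditionMessage(e))
    if (is.character(row)) {
      quarantined[clusterId(cl)] <- row
      warning("quarantining cluster ", clusterId(cl), ": ", row)
    } else {
      ok[i] <- TRUE
      featRows[[length(featRows) + 1L]] <- row
    }
  }
  if (!length(featRows)) {
    return(list(kept = list(), removed = list(), quarantined = quarantined,
                manifest = data.frame(clusterId = character(),
                                      probH = numeric(),
                                      decision = character())))
  }
  feats <- do.call(rbind, featRows)
  probH <- predict(model, feats, type = "prob")
  keep <- probH >= model@threshold
  okClusters <- clusters[ok]
  manifest <- data.frame(clusterId = feats$clusterId, probH = probH,
                         decision = ifelse(keep, "kept", "removed"),
                         stringsAsFactors = FALSE)
  list(kept = okClusters[keep], removed = okClusters[!keep],
       quarantined = quarantined, manifest = manifest)
}

#' Save / load a fitted classifier
#'
#' Single-file persistence with schema and seed metadata intact.
#'
#' @param model a [HomologyClassifier-class].
#' @param path file path.
#' @return \code{saveClassifier}: \code{path}, invisibly;
#'   \code{loadClassifier}: the model.
#' @export
saveClassifier <- function(model, path) {
  stopifnot(methods::is(model, "HomologyClassifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  model <- readRDS(path)
  stopifnot(methods::is(model, "HomologyClassifier"))
  model
}
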