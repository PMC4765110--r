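## Pipeline: simulate ground-truth cluster sets, featurize directories,
## and run the end-to-end workflow from one master seed.

#' Simulate a ground-truth training cluster set in memory
#'
#' Generates the five provenance classes: synthetic homology families
#' (\code{H_SYNTH}), random draws from the pooled homology members
#' (\code{NH_RANDOM}), and evolved decoys at 0/25/50 percent invariable
#' sites (\code{NH_EVOLVED_*}), each evolved cluster deriving from one
#' homology cluster. Class counts follow the EQUAL or PROP composition.
#' All randomness derives from \code{seed}, so the same seed reproduces
#' the same clusters.
#'
#' @param nTotal total cluster count (divisible by 5 for EQUAL, 8 for
#'   PROP).
#' @param scheme \code{"EQUAL"} or \code{"PROP"}.
#' @param seed master seed.
#' @param sizeLambda Poisson mean for cluster sizes (default 44.3056).
#' @param rootLengthRange root length range for synthetic homologs.
#' @param divergence homolog branch-length mean, substitutions/site.
#' @param tparams a [treeParams()] for the evolved decoys.
#' @param alnParams an [alignParams()].
#' @return Named list of aligned, labelled [HomologyCluster-class]
#'   objects.
#' @seealso [simulateTrainingSet()] for the on-disk variant.
#' @export
simulateClusters <- function(nTotal, scheme = c("EQUAL", "PROP"), seed = 1L,
                             sizeLambda = 44.3056,
                             rootLengthRange = c(120L, 400L),
                             divergence = 0.05,
                             tparams = treeParams(),
                             alnParams = alignParams()) {
  scheme <- match.arg(scheme)
  if (scheme == "EQUAL") {
    if (nTotal %% 5 != 0) stop("EQUAL composition needs nTotal divisible by 5")
    nH <- nTotal / 5; nPerNH <- nTotal / 5
  } else {
    if (nTotal %% 8 != 0) stop("PROP composition needs nTotal divisible by 8")
    nH <- nTotal / 2; nPerNH <- nTotal / 8
  }
  hs <- makeHSynthetic(nH, sizeLambda = sizeLambda,
                       rootLengthRange = rootLengthRange,
                       divergence = divergence,
                       seed = deriveSeed(seed, "h_synth"),
                       alnParams = alnParams)
  pool <- do.call(c, lapply(hs, members))
  names(pool) <- unlist(lapply(hs, function(h) names(members(h))))
  nhRandom <- lapply(seq_len(nPerNH), function(i)
    makeNHRandom(pool, nhGenParams(poissonLambda = sizeLambda,
                                   seed = deriveSeed(seed, paste0("nh_rand_", i))),
                 clusterId = sprintf("nh_random_%04d", i),
                 alnParams = alnParams))
  evolved <- list()
  for (pInv in c(0, 0.25, 0.5)) {
    model <- wagModel(pInv)
    stage <- sprintf("nh_ev_%d", as.integer(pInv * 100))
    src <- withLocalSeed(deriveSeed(seed, paste0(stage, "_src")),
                         sample.int(length(hs), nPerNH, replace = TRUE))
    evolved <- c(evolved, lapply(seq_len(nPerNH), function(i) {
      cl <- makeNHEvolved(hs[[src[i]]], model, tparams,
                          seed = deriveSeed(seed, paste0(stage, "_", i)),
                          alnParams = alnParams)
      cl@clusterId <- sprintf("%s_%04d", stage, i)
      cl
    }))
  }
  out <- c(hs, nhRandom, evolved)
  names(out) <- vapply(out, clusterId, "")
  out
}

#' Simulate a training set and write it to disk
#'
#' Writes one aligned FASTA per cluster under
#' \code{dir/<provenance>/<clusterId>.fasta} plus a \code{manifest.csv}
#' (clusterId, label, provenance, seed). Idempotent per seed.
#'
#' @param dir output directory (created if absent).
#' @inheritParams simulateClusters
#' @param ... passed to [simulateClusters()].
#' @return The manifest data.frame, invisibly.
#' @export
simulateTrainingSet <- function(dir, nTotal, scheme = c("EQUAL", "PROP"),
                                seed = 1L, ...) {
  clusters <- simulateClusters(nTotal, scheme, seed, ...)
  for (cl in clusters) {
    sub <- file.path(dir, provenance(cl))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    writeClusterFasta(cl, file.path(sub, paste0(clusterId(cl), ".fasta")),
                      aligned = TRUE)
  }
  manifest <- data.frame(
    clusterId = vapply(clusters, clusterId, ""),
    label = vapply(clusters, clusterLabel, ""),
    provenance = vapply(clusters, provenance, ""),
    seed = seed, stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Featurize a cluster directory
#'
#' Reads every cluster FASTA under \code{dir} (recursively), labels rows
#' from \code{manifest.csv} when present, and computes the ten features.
#'
#' @param dir directory written by [simulateTrainingSet()] or any
#'   directory of cluster FASTA files.
#' @param seed seed for the randomness scorer.
#' @param scheme an [aminoClassScheme()].
#' @param alnParams an [alignParams()].
#' @return Feature data.frame (see [featurizeClusters()]).
#' @export
featurizeDirectory <- function(dir, seed = 1L, scheme = aminoClassScheme(),
                               alnParams = alignParams()) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$",
                           full.names = TRUE, recursive = TRUE))
  if (!length(files)) stop("no cluster FASTA files under ", dir)
  clusters <- lapply(files, readClusterFasta)
  manifestPath <- file.path(dir, "manifest.csv")
  if (file.exists(manifestPath)) {
    mf <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
    clusters <- lapply(clusters, function(cl) {
      at <- match(clusterId(cl), mf$clusterId)
      if (!is.na(at)) {
        cl@label <- mf$label[at]
        cl@provenance <- mf$provenance[at]
      }
      cl
    })
  }
  featurizeClusters(clusters, scheme,
                    randomnessParams(seed = deriveSeed(seed, "randomness")),
                    alnParams)
}

#' Run the synthetic end-to-end experiment
#'
#' Simulate an EQUAL or PROP cluster set, featurize it, split 80/10/10,
#' train a classifier, and evaluate on the validation and test partitions
#' — the whole workflow under one master seed.
#'
#' @param nTotal total cluster count.
#' @param scheme \code{"EQUAL"} or \code{"PROP"}.
#' @param kind classifier kind (default the stacking meta-classifier with
#'   logistic regression).
#' @param seed master seed.
#' @param ... passed to [simulateClusters()].
#' @return List: \code{model}, \code{split}, \code{validation} and
#'   \code{test} \code{EvaluationReport}s, \code{features}.
#' @export
runSyntheticExperiment <- function(nTotal, scheme = "EQUAL",
                                   kind = "stack_with_lr", seed = 1L, ...) {
  clusters <- simulateClusters(nTotal, scheme, seed, ...)
  feats <- featurizeClusters(
    clusters, rparams = randomnessParams(seed = deriveSeed(seed, "randomness")))
  split <- splitDataset(feats, seed = deriveSeed(seed, "split"))
  model <- trainClassifier(kind, split$train,
                           seed = deriveSeed(seed, "train"))
  list(model = model, split = split,
       validation = evaluateClassifier(model, split$valid),
       test = evaluateClassifier(model, split$test),
       features = feats)
}
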