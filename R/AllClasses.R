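#' @import methods
#' @importFrom Biostrings AAStringSet width writeXStringSet readAAStringSet
NULL

#' HomologyCluster: a putative homology cluster of protein sequences
#'
#' The central data container: a named set of amino-acid sequences with an
#' optional multiple sequence alignment, a homology label, a provenance tag
#' recording how the cluster arose (real data or one of the generative
#' ground-truth routes), and an optional precomputed count of randomly
#' aligned alignment positions.
#'
#' @slot clusterId single string identifying the cluster.
#' @slot members \code{AAStringSet} of ungapped member sequences, uniquely
#'   named by gene/protein id.
#' @slot alignment \code{AAStringSet} of gapped rows (zero-length when the
#'   cluster has not been aligned); row ids match \code{members}, and
#'   removing gaps from each row recovers the member residues exactly.
#' @slot label one of \code{"H"}, \code{"NH"}, \code{"UNKNOWN"}.
#' @slot provenance one of \code{"REAL"}, \code{"NH_RANDOM"},
#'   \code{"NH_EVOLVED_0"}, \code{"NH_EVOLVED_25"}, \code{"NH_EVOLVED_50"},
#'   \code{"H_SYNTH"}.
#' @slot aliscore optional precomputed randomly-aligned-position count
#'   (\code{NA} when the internal scorer should be used).
#'
#' @seealso [HomologyCluster()] for construction,
#'   [readClusterFasta()] for file input.
#' @exportClass HomologyCluster
setClass("HomologyCluster",
  slots = c(
    clusterId  = "character",
    members    = "AAStringSet",
    alignment  = "AAStringSet",
    label      = "character",
    provenance = "character",
    aliscore   = "numeric"
  ),
  prototype = list(
    clusterId  = "cluster",
    label      = "UNKNOWN",
    provenance = "REAL",
    aliscore   = NA_real_
  )
)

setValidity("HomologyCluster", function(object) {
  msg <- character()
  if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
    msg <- c(msg, "clusterId must be a single non-empty string")
  if (length(object@members) < 2L)
    msg <- c(msg, "a cluster needs at least 2 members")
  nm <- names(object@members)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    msg <- c(msg, "members must carry unique, non-empty ids")
  if (any(Biostrings::width(object@members) < 1L))
    msg <- c(msg, "members must have ungapped length >= 1")
  if (any(grepl("-", as.character(object@members), fixed = TRUE)))
    msg <- c(msg, "members must be ungapped")
  if (length(object@label) != 1L || !object@label %in% CLUSTER_LABELS)
    msg <- c(msg, "label must be one of H / NH / UNKNOWN")
  if (length(object@provenance) != 1L ||
      !object@provenance %in% CLUSTER_PROVENANCES)
    msg <- c(msg, sprintf("provenance must be one of %s",
                          paste(CLUSTER_PROVENANCES, collapse = ", ")))
  if (length(object@alignment) > 0L) {
    if (length(unique(Biostrings::width(object@alignment))) != 1L)
      msg <- c(msg, "alignment rows must share one length")
    anm <- names(object@alignment)
    if (is.null(anm) || !setequal(anm, nm))
      msg <- c(msg, "alignment row ids must match member ids")
    else {
      dg <- as.character(degap(object@alignment))
      names(dg) <- anm
      if (!identical(dg[nm], stats::setNames(as.character(object@members), nm)))
        msg <- c(msg, "degapped alignment rows must equal member residues")
    }
  }
  if (length(object@aliscore) != 1L)
    msg <- c(msg, "aliscore must be a single number (or NA)")
  else if (!is.na(object@aliscore)) {
    if (length(object@alignment) == 0L)
      msg <- c(msg, "aliscore requires an alignment")
    else if (object@aliscore < 0 ||
             object@aliscore > Biostrings::width(object@alignment)[1L])
      msg <- c(msg, "aliscore must lie in [0, alignment length]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HomologyCluster
#'
#' @param members named \code{AAStringSet} (or named character vector) of
#'   ungapped amino-acid sequences; at least two.
#' @param clusterId single string id.
#' @param alignment optional named \code{AAStringSet} of gapped rows whose
#'   degapped residues equal \code{members}.
#' @param label cluster label, one of \code{"H"}, \code{"NH"},
#'   \code{"UNKNOWN"}.
#' @param provenance provenance tag (see class documentation).
#' @param aliscore optional precomputed randomly-aligned-position count.
#' @return A validated [HomologyCluster-class] object.
#' @examples
#' cl <- HomologyCluster(c(s1 = "MKLV", s2 = "MKIV"))
#' nSequences(cl)
#' @export
HomologyCluster <- function(members, clusterId = "cluster",
                            alignment = NULL, label = "UNKNOWN",
                            provenance = "REAL", aliscore = NA_real_) {
  if (is.character(members))
    members <- Biostrings::AAStringSet(members)
  if (is.null(alignment))
    alignment <- Biostrings::AAStringSet()
  else if (is.character(alignment))
    alignment <- Biostrings::AAStringSet(alignment)
  methods::new("HomologyCluster",
               clusterId = clusterId, members = members,
               alignment = alignment, label = label,
               provenance = provenance, aliscore = as.numeric(aliscore))
}

#' HomologyClassifier: a fitted homology-vs-non-homology classifier
#'
#' Holds a fitted base classifier or stacking ensemble together with its
#' feature schema (locked at fit time and enforced at prediction time),
#' feature standardisation parameters, decision threshold and seed.
#'
#' @slot kind one of \code{"mlp"}, \code{"svm"}, \code{"random_forest"},
#'   \code{"naive_bayes"}, \code{"logistic"}, \code{"stack_with_lr"},
#'   \code{"stack_without_lr"}.
#' @slot fit fitted model object (for base kinds).
#' @slot baseFits named list of fitted base models (for stacking kinds).
#' @slot meta fitted meta-classifier (for stacking kinds).
#' @slot baseKinds character vector of base-model kinds used by a stack.
#' @slot schema ordered character vector of feature names.
#' @slot center,scale numeric vectors used to standardise features.
#' @slot threshold probability-of-H cutoff below which a cluster is
#'   classified NH (default 0.5).
#' @slot seed integer seed the model was fitted under.
#' @exportClass HomologyClassifier
setClass("HomologyClassifier",
  slots = c(
    kind      = "character",
    fit       = "ANY",
    baseFits  = "list",
    meta      = "ANY",
    baseKinds = "character",
    schema    = "character",
    center    = "numeric",
    scale     = "numeric",
    threshold = "numeric",
    seed      = "numeric"
  ),
  prototype = list(threshold = 0.5, seed = NA_real_)
)

setValidity("HomologyClassifier", function(object) {
  msg <- character()
  if (!object@kind %in% CLASSIFIER_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(CLASSIFIER_KINDS, collapse = ", ")))
  if (length(object@schema) < 1L)
    msg <- c(msg, "schema must name at least one feature")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

CLASSIFIER_KINDS <- c("mlp", "svm", "random_forest", "naive_bayes",
                      "logistic", "stack_with_lr", "stack_without_lr")
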