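## features: the ten alignment-level attributes of a cluster.

#' Physicochemical amino-acid class scheme
#'
#' Bins the 20 standard residues into four disjoint classes (charged,
#' uncharged/polar, hydrophobic, special). The default assignment follows
#' the standard physicochemical grouping; pass your own sets to swap
#' assignments (e.g. to move histidine out of the charged class).
#'
#' @param charged,uncharged,hydrophobic,special character vectors of
#'   one-letter residue codes; must be disjoint and jointly cover the 20
#'   standard amino acids.
#' @return A validated list of class \code{AminoClassScheme}.
#' @examples
#' sch <- aminoClassScheme()
#' sch$charged
#' @export
aminoClassScheme <- function(charged = c("D", "E", "K", "R", "H"),
                             uncharged = c("S", "T", "N", "Q", "Y"),
                             hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
                             special = c("C", "G", "P")) {
  sets <- list(charged = charged, uncharged = uncharged,
               hydrophobic = hydrophobic, special = special)
  all <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all))
    stop("amino-acid classes must be disjoint")
  if (!setequal(all, AA20))
    stop("amino-acid classes must jointly cover the 20 standard residues")
  structure(sets, class = "AminoClassScheme")
}

#' Count gap characters in an alignment
#'
#' @param aln gapped \code{AAStringSet} (or an aligned
#'   [HomologyCluster-class]).
#' @return Total number of \code{-} characters over the whole matrix.
#' @examples
#' countGaps(Biostrings::AAStringSet(c("AC-", "A--")))
#' @export
countGaps <- function(aln) {
  aln <- asAlignmentSet(aln)
  sum(Biostrings::letterFrequency(aln, "-"))
}

#' Count amino-acid residues in an alignment
#'
#' Non-gap characters (unknown residues \code{X} included), so
#' \code{countGaps(a) + countAminoAcids(a) = columns * rows}.
#'
#' @inheritParams countGaps
#' @return Total number of non-gap characters.
#' @export
countAminoAcids <- function(aln) {
  aln <- asAlignmentSet(aln)
  length(aln) * Biostrings::width(aln)[1L] - countGaps(aln)
}

asAlignmentSet <- function(aln) {
  if (methods::is(aln, "HomologyCluster")) {
    if (!hasAlignment(aln))
      stop("cluster ", clusterId(aln), " is not aligned")
    aln <- alignment(aln)
  }
  stopifnot(methods::is(aln, "XStringSet"),
            length(unique(Biostrings::width(aln))) == 1L)
  aln
}

#' Range of ungapped member lengths
#'
#' Longest minus shortest unaligned sequence length within the cluster.
#'
#' @param x a [HomologyCluster-class].
#' @return Non-negative integer.
#' @export
sequenceRange <- function(x) {
  stopifnot(methods::is(x, "HomologyCluster"))
  w <- Biostrings::width(members(x))
  as.integer(max(w) - min(w))
}

#' Compositional dispersion of one physicochemical class
#'
#' For each row, the proportion of its countable residues (non-gap,
#' non-\code{X}) falling in the class; the dispersion is the square root of
#' the unbiased (Bessel, n-1) variance of these proportions across rows.
#' Computing proportions over each sequence's own residue count corrects
#' for sequence length.
#'
#' @inheritParams countGaps
#' @param scheme an [aminoClassScheme()].
#' @param cls one of \code{"charged"}, \code{"uncharged"},
#'   \code{"hydrophobic"}, \code{"special"}.
#' @return Non-negative standard deviation of per-row class proportions.
#' @examples
#' aln <- Biostrings::AAStringSet(c("DE", "AA"))
#' classDispersion(aln, cls = "charged")  # sqrt(.5)
#' @export
classDispersion <- function(aln, scheme = aminoClassScheme(),
                            cls = c("charged", "uncharged", "hydrophobic",
                                    "special")) {
  cls <- match.arg(cls)
  p <- classProportions(aln, scheme)
  stats::sd(p[, cls])
}

## per-row class proportion matrix (rows = sequences, cols = 4 classes)
classProportions <- function(aln, scheme = aminoClassScheme()) {
  aln <- asAlignmentSet(aln)
  stopifnot(length(aln) >= 2L, inherits(scheme, "AminoClassScheme"))
  counts <- vapply(scheme, function(set)
    rowSums(Biostrings::letterFrequency(aln, set)), numeric(length(aln)))
  countable <- rowSums(counts)
  if (any(countable == 0)) {
    bad <- which(countable == 0)[1L]
    id <- if (!is.null(names(aln))) names(aln)[bad] else paste("row", bad)
    stop("sequence '", id, "' has no countable (non-gap, non-X) residues")
  }
  counts / countable
}

#' Compute the ten-attribute feature vector of a cluster
#'
#' The attributes of a cluster's MSA used for homology-vs-non-homology
#' classification: the randomly-aligned-position count (precomputed value
#' if attached, else the internal Monte-Carlo scorer), alignment length,
#' number of sequences, gap count, residue count, ungapped-length range,
#' and the compositional dispersion of the four physicochemical classes.
#'
#' @param x an aligned [HomologyCluster-class] (align first otherwise, see
#'   [progressiveAlign()]).
#' @param scheme an [aminoClassScheme()].
#' @param rparams a [randomnessParams()]; its seed makes the vector
#'   deterministic.
#' @return Named numeric vector with elements \code{aliscore},
#'   \code{length}, \code{n_sequences}, \code{n_gaps},
#'   \code{n_amino_acids}, \code{range}, \code{sd_charged},
#'   \code{sd_uncharged}, \code{sd_special}, \code{sd_hydrophobic}.
#' @examples
#' cl <- HomologyCluster(c(a = "MKDE", b = "MKDE"),
#'                       alignment = c(a = "MKDE", b = "MKDE"))
#' clusterFeatures(cl, rparams = randomnessParams(seed = 1))
#' @seealso [featurizeClusters()] for whole cluster sets.
#' @export
clusterFeatures <- function(x, scheme = aminoClassScheme(),
                            rparams = randomnessParams()) {
  stopifnot(methods::is(x, "HomologyCluster"))
  if (!hasAlignment(x))
    stop("cluster ", clusterId(x), " is not aligned; align it first")
  aln <- alignment(x)
  ali <- if (!is.na(aliscoreValue(x))) aliscoreValue(x)
         else randomPositions(aln, rparams)
  c(aliscore       = as.numeric(ali),
    length         = as.numeric(Biostrings::width(aln)[1L]),
    n_sequences    = as.numeric(length(aln)),
    n_gaps         = as.numeric(countGaps(aln)),
    n_amino_acids  = as.numeric(countAminoAcids(aln)),
    range          = as.numeric(sequenceRange(x)),
    sd_charged     = classDispersion(aln, scheme, "charged"),
    sd_uncharged   = classDispersion(aln, scheme, "uncharged"),
    sd_special     = classDispersion(aln, scheme, "special"),
    sd_hydrophobic = classDispersion(aln, scheme, "hydrophobic"))
}

FEATURE_NAMES <- c("aliscore", "length", "n_sequences", "n_gaps",
                   "n_amino_acids", "range", "sd_charged", "sd_uncharged",
                   "sd_special", "sd_hydrophobic")

#' Featurize a list of clusters into a table
#'
#' Aligns any unaligned cluster, then computes [clusterFeatures()] for
#' each. Per-cluster randomness seeds are derived from \code{seed} and the
#' cluster id, so the table is reproducible regardless of list order.
#'
#' @param clusters list of [HomologyCluster-class] objects.
#' @param scheme an [aminoClassScheme()].
#' @param rparams a [randomnessParams()] (per-cluster seeds are derived
#'   from its \code{seed} unless the cluster carries a precomputed count).
#' @param alnParams an [alignParams()] used when alignment is needed.
#' @return data.frame with columns \code{clusterId}, \code{label},
#'   \code{provenance} and the ten feature columns.
#' @export
featurizeClusters <- function(clusters, scheme = aminoClassScheme(),
                              rparams = randomnessParams(seed = 1),
                              alnParams = alignParams()) {
  stopifnot(is.list(clusters), length(clusters) >= 1L)
  rows <- lapply(clusters, function(cl) {
    cl <- ensureAligned(cl, alnParams)
    rp <- rparams
    if (!is.na(rparams$seed))
      rp$seed <- deriveSeed(rparams$seed, clusterId(cl))
    fv <- clusterFeatures(cl, scheme, rp)
    cbind(data.frame(clusterId = clusterId(cl), label = clusterLabel(cl),
                     provenance = provenance(cl), stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV
#'
#' @param features data.frame from [featurizeClusters()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
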