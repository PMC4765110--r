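## randomness: Monte-Carlo sliding-window count of randomly aligned
## alignment positions.
##
## A consistent randomness signal standing in the place the ALISCORE value
## occupies in the feature vector: parametric Monte-Carlo resampling within
## a sliding window, scored with BLOSUM62 and decided per column by a
## majority vote over covering windows. It does not reproduce the external
## program's match-probability model or output lists.

#' Parameters of the alignment-randomness scorer
#'
#' @param window sliding-window width in columns (default 6; >= 2).
#' @param nResamples Monte-Carlo resamples per sequence pair
#'   (default 100; >= 10).
#' @param quantile null-distribution quantile a window's observed score
#'   must exceed to count as non-random (default 0.95).
#' @param gapScore additive score contributed by a gap-containing column
#'   pair (default -1). Gap columns are penalised, not skipped:
#'   non-homology clusters are gap-rich and the count is expected to be
#'   higher for them.
#' @param seed integer seed making the count deterministic (\code{NA} uses
#'   the ambient RNG stream).
#' @return A validated list of class \code{RandomnessParams}.
#' @examples
#' randomnessParams(seed = 1)$window
#' @export
randomnessParams <- function(window = 6L, nResamples = 100L,
                             quantile = 0.95, gapScore = -1,
                             seed = NA_integer_) {
  stopifnot(window >= 2L, nResamples >= 10L,
            quantile > 0, quantile < 1, is.numeric(gapScore))
  structure(list(window = as.integer(window),
                 nResamples = as.integer(nResamples),
                 quantile = quantile, gapScore = gapScore,
                 seed = seed),
            class = "RandomnessParams")
}

#' Count randomly aligned alignment positions
#'
#' For every unordered pair of rows and every sliding-window start, the
#' observed score is the BLOSUM62 sum over the window's column pairs (a
#' gap-containing column contributes \code{gapScore}). The pair's null
#' distribution is the score of \code{nResamples} windows whose residues
#' are drawn independently from each row's own ungapped residue
#' frequencies; a window is non-random iff its observed score exceeds the
#' null quantile. A column is flagged random iff, pooled over all pairs,
#' fewer than half of the windows covering it are non-random.
#'
#' The result is invariant to row order and id relabeling, and
#' deterministic given \code{params$seed}.
#'
#' @param aln gapped \code{AAStringSet} with >= 2 rows (or an aligned
#'   [HomologyCluster-class]).
#' @param params a [randomnessParams()].
#' @return Flagged-column count in \code{[0, alignment length]}.
#' @examples
#' aln <- Biostrings::AAStringSet(c(a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
#'                                  b = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"))
#' randomPositions(aln, randomnessParams(seed = 1))
#' @export
randomPositions <- function(aln, params = randomnessParams()) {
  aln <- asAlignmentSet(aln)
  n <- length(aln)
  stopifnot(n >= 2L)
  L <- Biostrings::width(aln)[1L]
  w <- params$window
  if (w > L) {
    message("window (", w, ") exceeds alignment length (", L,
            "); scoring the whole alignment as one window")
    w <- L
  }
  B <- blosum62()
  mat <- asResidueMatrix(aln)
  idx <- matrix(match(mat, rownames(B)), nrow = n)  # NA for gaps
  rowRes <- lapply(seq_len(n), function(i) idx[i, !is.na(idx[i, ])])

  starts <- seq_len(L - w + 1L)
  nStarts <- length(starts)
  ## windows covering column c: starts in [c - w + 1, c] clipped to range
  covPerCol <- pmin(seq_len(L), nStarts, w, L - seq_len(L) + 1L)

  withLocalSeed(params$seed, {
    nonrandCov <- numeric(L)
    nPairs <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        nPairs <- nPairs + 1L
        colScore <- B[cbind(idx[i, ], idx[j, ])]
        colScore[is.na(colScore)] <- params$gapScore
        cs <- cumsum(colScore)
        winScore <- cs[starts + w - 1L] - c(0, cs)[starts]
        ri <- rowRes[[i]][sample.int(length(rowRes[[i]]),
                                     params$nResamples * w, replace = TRUE)]
        rj <- rowRes[[j]][sample.int(length(rowRes[[j]]),
                                     params$nResamples * w, replace = TRUE)]
        nullScore <- rowSums(matrix(B[cbind(ri, rj)],
                                    nrow = params$nResamples))
        thr <- stats::quantile(nullScore, params$quantile, names = FALSE)
        nonrand <- as.numeric(winScore > thr)
        ## per-column count of covering non-random windows
        cn <- cumsum(nonrand)
        hi <- pmin(seq_len(L), nStarts)
        lo <- pmax(seq_len(L) - w + 1L, 1L)
        nonrandCov <- nonrandCov + (cn[hi] - c(0, cn)[lo])
      }
    }
    sum(nonrandCov < 0.5 * nPairs * covPerCol)
  })
}
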