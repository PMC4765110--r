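## msa_align: pairwise and progressive protein alignment.
##
## The progressive aligner exists so the package runs self-contained; its
## outputs feed alignment-level statistics, so any reasonable MSA suffices.
## An external-aligner hook (e.g. MAFFT) is provided for users who prefer it.

.pkgCache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkgCache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$B62 <- e$BLOSUM62
  }
  .pkgCache$B62
}

## profile alphabet: BLOSUM62 letters minus the stop character
profileLetters <- function(mat) setdiff(rownames(mat), "*")

#' Alignment scoring parameters
#'
#' Affine gap costs: a maximal gap run of length \eqn{k} costs
#' \code{gapOpen + (k - 1) * gapExtend}.
#'
#' @param substitutionMatrix symmetric integer substitution matrix
#'   (default BLOSUM62, the standard protein scoring matrix).
#' @param gapOpen gap opening score, negative (default -10).
#' @param gapExtend gap extension score, negative,
#'   \code{gapOpen <= gapExtend < 0} (default -1).
#' @return A validated list of class \code{AlignParams}.
#' @examples
#' p <- alignParams()
#' p$gapOpen
#' @export
alignParams <- function(substitutionMatrix = NULL, gapOpen = -10,
                        gapExtend = -1) {
  if (is.null(substitutionMatrix)) substitutionMatrix <- blosum62()
  stopifnot(is.matrix(substitutionMatrix),
            identical(rownames(substitutionMatrix),
                      colnames(substitutionMatrix)),
            isTRUE(all.equal(substitutionMatrix, t(substitutionMatrix))),
            gapExtend < 0, gapOpen <= gapExtend)
  structure(list(substitutionMatrix = substitutionMatrix,
                 gapOpen = gapOpen, gapExtend = gapExtend),
            class = "AlignParams")
}

## One-hot / frequency profile of a residue character matrix.
## Rows of the result = profile letters, columns = alignment columns;
## columns sum to the fraction of non-gap rows (gap mass carries no score).
residueProfile <- function(mat, letters) {
  pr <- matrix(0, nrow = length(letters), ncol = ncol(mat),
               dimnames = list(letters, NULL))
  for (ch in intersect(unique(as.vector(mat)), letters))
    pr[ch, ] <- colSums(mat == ch)
  pr / nrow(mat)
}

## Score matrix between two profiles under a substitution matrix.
profileScores <- function(prA, prB, subMat) {
  letters <- rownames(prA)
  crossprod(prA, subMat[letters, letters] %*% prB)
}

## Run the affine DP on two residue matrices; returns merged matrix + score.
mergeProfiles <- function(matA, matB, params) {
  letters <- profileLetters(params$substitutionMatrix)
  S <- profileScores(residueProfile(matA, letters),
                     residueProfile(matB, letters),
                     params$substitutionMatrix)
  res <- .affineAlign(S, params$gapOpen, params$gapExtend)
  k <- length(res$aIndex)
  out <- matrix("-", nrow = nrow(matA) + nrow(matB), ncol = k)
  out[seq_len(nrow(matA)), res$aIndex > 0L] <- matA[, res$aIndex[res$aIndex > 0L], drop = FALSE]
  out[nrow(matA) + seq_len(nrow(matB)), res$bIndex > 0L] <- matB[, res$bIndex[res$bIndex > 0L], drop = FALSE]
  rownames(out) <- c(rownames(matA), rownames(matB))
  list(mat = out, score = res$score)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment of two ungapped protein
#' sequences. Ties in the dynamic program are broken deterministically
#' (diagonal, then up, then left).
#'
#' @param a,b named character scalars or \code{AAString}/length-1
#'   \code{AAStringSet}; ungapped.
#' @param params an [alignParams()] object.
#' @return A list with elements \code{alignment} (2-row gapped
#'   \code{AAStringSet}) and \code{score} (optimal global score).
#' @examples
#' pairwiseAlign(c(x = "HEAGAWGHEE"), c(y = "PAWHEAE"))$score
#' @export
pairwiseAlign <- function(a, b, params = alignParams()) {
  toChr <- function(x, fallback) {
    nm <- names(x)
    v <- as.character(x)
    if (!is.null(nm) && nzchar(nm[1L])) names(v) <- nm
    else if (is.null(names(v)) || !nzchar(names(v)[1L])) names(v) <- fallback
    v
  }
  a <- toChr(a, "seq1"); b <- toChr(b, "seq2")
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  if (grepl("-", paste0(a, b), fixed = TRUE))
    stop("pairwiseAlign expects ungapped sequences")
  matA <- matrix(strsplit(toupper(a), "")[[1L]], nrow = 1,
                 dimnames = list(names(a), NULL))
  matB <- matrix(strsplit(toupper(b), "")[[1L]], nrow = 1,
                 dimnames = list(names(b), NULL))
  m <- mergeProfiles(matA, matB, params)
  list(alignment = matrixToAlignment(m$mat), score = m$score)
}

matrixToAlignment <- function(mat) {
  out <- Biostrings::AAStringSet(apply(mat, 1L, paste, collapse = ""))
  names(out) <- rownames(mat)
  out
}

## k-mer cosine distance between ungapped sequences (guide-tree metric)
kmerDistances <- function(chars, k = 3L) {
  k <- max(1L, min(k, min(nchar(chars))))
  counts <- lapply(chars, function(s) {
    n <- nchar(s)
    table(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  kmers <- unique(unlist(lapply(counts, names)))
  V <- vapply(counts, function(tb) {
    v <- numeric(length(kmers)); names(v) <- kmers
    v[names(tb)] <- as.numeric(tb); v
  }, numeric(length(kmers)))
  V <- matrix(V, nrow = length(kmers))
  nrm <- sqrt(colSums(V^2))
  cosSim <- crossprod(V) / outer(nrm, nrm)
  d <- 1 - cosSim
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Progressive multiple alignment of a cluster
#'
#' Aligns cluster members progressively along a UPGMA guide tree built on
#' 3-mer cosine distances, merging profiles with mean-of-pairs scoring and
#' the affine-gap dynamic program of [pairwiseAlign()]. Residues are never
#' permuted, dropped or mutated: removing the gaps from each output row
#' recovers the input sequences exactly.
#'
#' @param x a [HomologyCluster-class] with at least 2 members.
#' @param params an [alignParams()] object.
#' @return The cluster with its \code{alignment} slot populated.
#' @examples
#' cl <- HomologyCluster(c(a = "MKLVW", b = "MKLW", c = "MKLVW"))
#' alignment(progressiveAlign(cl))
#' @seealso [externalAlign()] for delegating to an installed aligner.
#' @export
progressiveAlign <- function(x, params = alignParams()) {
  stopifnot(methods::is(x, "HomologyCluster"))
  chars <- as.character(members(x))
  ids <- names(members(x))
  if (length(chars) == 2L) {
    pa <- pairwiseAlign(stats::setNames(chars[1L], ids[1L]),
                        stats::setNames(chars[2L], ids[2L]), params)
    x@alignment <- pa$alignment[ids]
    methods::validObject(x)
    return(x)
  }
  hc <- stats::hclust(kmerDistances(chars), method = "average")
  mats <- lapply(seq_along(chars), function(i)
    matrix(strsplit(chars[i], "")[[1L]], nrow = 1,
           dimnames = list(ids[i], NULL)))
  grown <- vector("list", nrow(hc$merge))
  pick <- function(idx) if (idx < 0) mats[[-idx]] else grown[[idx]]
  for (s in seq_len(nrow(hc$merge)))
    grown[[s]] <- mergeProfiles(pick(hc$merge[s, 1L]),
                                pick(hc$merge[s, 2L]), params)$mat
  final <- grown[[nrow(hc$merge)]][ids, , drop = FALSE]
  x@alignment <- matrixToAlignment(final)
  methods::validObject(x)
  x
}

#' Align a cluster with an external aligner
#'
#' Writes the unaligned members to a temporary FASTA, substitutes the
#' \code{{in}} and \code{{out}} placeholders of \code{commandTemplate},
#' runs the command through the shell, and reads the aligned FASTA back.
#' The degapping-identity contract of [progressiveAlign()] is enforced on
#' the result.
#'
#' @param x a [HomologyCluster-class].
#' @param commandTemplate shell command with \code{{in}} and \code{{out}}
#'   placeholders, e.g. \code{"mafft --auto {in} > {out}"}.
#' @return The cluster with its \code{alignment} slot populated.
#' @export
externalAlign <- function(x, commandTemplate) {
  stopifnot(methods::is(x, "HomologyCluster"),
            is.character(commandTemplate), length(commandTemplate) == 1L)
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  Biostrings::writeXStringSet(members(x), fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, commandTemplate,
                                  fixed = TRUE), fixed = TRUE)
  ferr <- tempfile()
  status <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = NULL, stderr = ferr))
  errTxt <- if (file.exists(ferr)) paste(readLines(ferr, warn = FALSE),
                                         collapse = "\n") else ""
  unlink(ferr)
  if (!identical(status, 0L))
    stop("external aligner failed (exit ", status, "): ", errTxt)
  aln <- tryCatch(Biostrings::readAAStringSet(fout),
                  error = function(e)
                    stop("unparsable external aligner output: ",
                         conditionMessage(e)))
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln <- Biostrings::AAStringSet(toupper(as.character(aln)))
  if (!setequal(names(aln), names(members(x))))
    stop("external aligner changed the sequence id set")
  x@alignment <- aln[names(members(x))]
  methods::validObject(x)
  x
}

## Ensure a cluster is aligned, using params when it is not.
ensureAligned <- function(x, params = alignParams()) {
  if (hasAlignment(x)) x else progressiveAlign(x, params)
}
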