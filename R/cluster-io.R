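## cluster_io: FASTA cluster reading/writing and pairwise relation input.

#' Read one putative homology cluster from a multi-FASTA file
#'
#' Input is case-insensitive and stored uppercase. Stop codons (\code{*})
#' are stripped with a warning (predicted proteomes commonly carry trailing
#' stops). The file is treated as aligned iff all records share one length
#' and at least one contains a gap, or \code{aligned = TRUE} forces it;
#' this avoids misreading equal-length unaligned ORFs as an alignment.
#'
#' @param path path to a multi-FASTA file with at least two records.
#' @param aligned \code{NA} (auto-detect, the default), or \code{TRUE} /
#'   \code{FALSE} to force the interpretation.
#' @param clusterId cluster id; defaults to the file name without extension.
#' @return A [HomologyCluster-class] with label \code{UNKNOWN}; the
#'   alignment slot is populated when the input is (detected as) aligned.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MK-L", ">b", "MKIL"), tf)
#' cl <- readClusterFasta(tf)
#' hasAlignment(cl)
#' @seealso [writeClusterFasta()]
#' @export
readClusterFasta <- function(path, aligned = NA,
                             clusterId = sub("\\.[^.]*$", "", basename(path))) {
  seqs <- Biostrings::readBStringSet(path)  # raw: validate residues ourselves
  if (length(seqs) < 2L)
    stop("malformed cluster '", path, "': fewer than 2 FASTA records")
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  names(chars) <- NULL
  if (any(grepl("*", chars, fixed = TRUE))) {
    warning("stripping '*' stop codons in ", path)
    chars <- gsub("*", "", chars, fixed = TRUE)
  }
  bad <- grepl(sprintf("[^%s-]", paste(setdiff(LEGAL_RESIDUES, "-"),
                                       collapse = "")), chars)
  if (any(bad)) {
    offending <- gsub(sprintf("[%s-]", paste(setdiff(LEGAL_RESIDUES, "-"),
                                             collapse = "")), "",
                      chars[which(bad)[1L]])
    stop("illegal residue character(s) '",
         paste(unique(strsplit(offending, "")[[1L]]), collapse = ""),
         "' in record '", ids[which(bad)[1L]], "' of ", path)
  }
  names(chars) <- ids
  widths <- nchar(chars)
  hasGap <- any(grepl("-", chars, fixed = TRUE))
  isAligned <- if (is.na(aligned)) {
    length(unique(widths)) == 1L && hasGap
  } else isTRUE(aligned)
  if (isAligned && length(unique(widths)) != 1L)
    stop("cannot treat ", path, " as aligned: records differ in length")
  if (isAligned) {
    aln <- Biostrings::AAStringSet(chars)
    mem <- degap(aln)
    names(mem) <- ids
    HomologyCluster(mem, clusterId = clusterId, alignment = aln)
  } else {
    if (hasGap) {
      warning("gap characters in unaligned input ", path, "; removing them")
      chars <- gsub("-", "", chars, fixed = TRUE)
    }
    HomologyCluster(Biostrings::AAStringSet(chars), clusterId = clusterId)
  }
}

#' Write a cluster to a multi-FASTA file
#'
#' Round-trips with [readClusterFasta()]: ids and residues are preserved
#' exactly.
#'
#' @param x a [HomologyCluster-class].
#' @param path output file path.
#' @param aligned write the gapped alignment rows instead of the ungapped
#'   members; requires the cluster to be aligned.
#' @return \code{path}, invisibly.
#' @export
writeClusterFasta <- function(x, path, aligned = FALSE) {
  stopifnot(methods::is(x, "HomologyCluster"))
  if (aligned && !hasAlignment(x))
    stop("cluster ", clusterId(x),
         " has no alignment; cannot write aligned FASTA")
  out <- if (aligned) alignment(x)[names(members(x))] else members(x)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read pairwise homology relations
#'
#' Reads the two-column output of pairwise orthology predictors (gene-id
#' pairs, one per line, tab- or whitespace-separated). Lines starting with
#' \code{#} are ignored. The relation is symmetric: duplicate and reversed
#' pairs are deduplicated, and self-pairs are dropped with a warning.
#'
#' @param path path to the relations file.
#' @return A data.frame with columns \code{geneA}, \code{geneB}, one row
#'   per unique unordered pair.
#' @examples
#' tf <- tempfile()
#' writeLines(c("g1\tg2", "g2\tg1", "g2\tg3"), tf)
#' readRelations(tf)
#' @seealso [transitiveClosure()]
#' @export
readRelations <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nn <- lengths(toks)
  if (any(nn != 2L)) {
    lineNo <- which(keep)[which(nn != 2L)[1L]]
    stop("relations parse error at line ", lineNo, " of ", path, ": expected ",
         "2 tokens, found ", nn[nn != 2L][1L])
  }
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", 2L)
  self <- a == b
  if (any(self)) {
    warning("dropping ", sum(self), " self-pair(s) in ", path)
    a <- a[!self]; b <- b[!self]
  }
  if (!length(a))
    return(data.frame(geneA = character(), geneB = character(),
                      stringsAsFactors = FALSE))
  lo <- pmin(a, b); hi <- pmax(a, b)
  keepRow <- !duplicated(paste0(lo, "\r", hi))
  data.frame(geneA = lo[keepRow], geneB = hi[keepRow],
             stringsAsFactors = FALSE)
}

#' Read a directory of cluster FASTA files
#'
#' The bulk input unit: one multi-FASTA per cluster.
#'
#' @param dir directory containing \code{.fa}/\code{.fasta} files.
#' @param aligned passed through to [readClusterFasta()].
#' @return Named list of [HomologyCluster-class] objects.
#' @export
readClusterDirectory <- function(dir, aligned = NA) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$",
                           full.names = TRUE))
  if (!length(files)) stop("no .fa/.fasta files found in ", dir)
  out <- lapply(files, readClusterFasta, aligned = aligned)
  names(out) <- vapply(out, clusterId, "")
  out
}
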