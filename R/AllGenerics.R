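#' Accessors for HomologyCluster objects
#'
#' @param x a [HomologyCluster-class].
#' @param value replacement value.
#' @return \code{clusterId}, \code{clusterLabel} and \code{provenance}
#'   return single strings; \code{members} and \code{alignment} return
#'   \code{AAStringSet}s (\code{alignment} is zero-length when unset);
#'   \code{nSequences} returns an integer; \code{hasAlignment} a logical;
#'   \code{aliscoreValue} a number or \code{NA}.
#' @examples
#' cl <- HomologyCluster(c(a = "MKL", b = "MKI"))
#' clusterId(cl); nSequences(cl); hasAlignment(cl)
#' @name cluster-accessors
NULL

#' @rdname cluster-accessors
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))
#' @rdname cluster-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname cluster-accessors
#' @export
setGeneric("alignment", function(x) standardGeneric("alignment"))
#' @rdname cluster-accessors
#' @export
setGeneric("hasAlignment", function(x) standardGeneric("hasAlignment"))
#' @rdname cluster-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname cluster-accessors
#' @export
setGeneric("clusterLabel", function(x) standardGeneric("clusterLabel"))
#' @rdname cluster-accessors
#' @export
setGeneric("clusterLabel<-", function(x, value) standardGeneric("clusterLabel<-"))
#' @rdname cluster-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname cluster-accessors
#' @export
setGeneric("aliscoreValue", function(x) standardGeneric("aliscoreValue"))

#' @rdname cluster-accessors
setMethod("clusterId", "HomologyCluster", function(x) x@clusterId)
#' @rdname cluster-accessors
setMethod("members", "HomologyCluster", function(x) x@members)
#' @rdname cluster-accessors
setMethod("alignment", "HomologyCluster", function(x) x@alignment)
#' @rdname cluster-accessors
setMethod("hasAlignment", "HomologyCluster",
          function(x) length(x@alignment) > 0L)
#' @rdname cluster-accessors
setMethod("nSequences", "HomologyCluster", function(x) length(x@members))
#' @rdname cluster-accessors
setMethod("clusterLabel", "HomologyCluster", function(x) x@label)
#' @rdname cluster-accessors
setMethod("clusterLabel<-", "HomologyCluster", function(x, value) {
  x@label <- value
  methods::validObject(x)
  x
})
#' @rdname cluster-accessors
setMethod("provenance", "HomologyCluster", function(x) x@provenance)
#' @rdname cluster-accessors
setMethod("aliscoreValue", "HomologyCluster", function(x) x@aliscore)

#' Attach a precomputed randomly-aligned-position count to a cluster
#'
#' Users running the external ALISCORE program can supply its per-cluster
#' count of randomly aligned positions; [clusterFeatures()] then uses the
#' supplied value verbatim instead of the internal Monte-Carlo scorer.
#'
#' @param x an aligned [HomologyCluster-class].
#' @param value count in \code{[0, alignment length]}.
#' @return The cluster with the value attached.
#' @examples
#' cl <- HomologyCluster(c(a = "MKL", b = "MKI"),
#'                       alignment = c(a = "MKL", b = "MKI"))
#' cl <- attachAliscore(cl, 1)
#' aliscoreValue(cl)
#' @export
attachAliscore <- function(x, value) {
  stopifnot(methods::is(x, "HomologyCluster"))
  if (!hasAlignment(x))
    stop("cluster ", clusterId(x), " has no alignment; align it first")
  len <- Biostrings::width(alignment(x))[1L]
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > len)
    stop("aliscore value must lie in [0, ", len, "] for cluster ",
         clusterId(x))
  x@aliscore <- as.numeric(value)
  methods::validObject(x)
  x
}

setMethod("show", "HomologyCluster", function(object) {
  cat("HomologyCluster '", object@clusterId, "'\n", sep = "")
  cat("  members   : ", length(object@members), " sequences (ungapped ",
      min(Biostrings::width(object@members)), "-",
      max(Biostrings::width(object@members)), " aa)\n", sep = "")
  if (hasAlignment(object))
    cat("  alignment : ", Biostrings::width(object@alignment)[1L],
        " columns\n", sep = "")
  else
    cat("  alignment : <none>\n")
  cat("  label     : ", object@label, " (", object@provenance, ")\n",
      sep = "")
  if (!is.na(object@aliscore))
    cat("  aliscore  : ", object@aliscore, " (precomputed)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "HomologyClassifier", function(object) {
  cat("HomologyClassifier (", object@kind, ")\n", sep = "")
  if (length(object@baseKinds))
    cat("  base models : ", paste(object@baseKinds, collapse = ", "), "\n",
        sep = "")
  cat("  features    : ", paste(object@schema, collapse = ", "), "\n",
      sep = "")
  cat("  threshold   : P(H) < ", object@threshold, " => NH\n", sep = "")
  invisible(NULL)
})
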