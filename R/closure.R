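## closure: homology clusters from pairwise relations by transitive closure.

#' Transitive closure of pairwise homology relations
#'
#' If A is related to B and B is related to C, then A is related to C:
#' clusters are the connected components of the relation graph. Components
#' are returned with sorted members and ordered by their lexicographically
#' smallest member id, so the result is deterministic and invariant to
#' input-line order.
#'
#' @param relations data.frame with columns \code{geneA}, \code{geneB}
#'   (as from [readRelations()]).
#' @return A list of class \code{ClusterPartition} with elements
#'   \code{components} (list of sorted id vectors, each of size >= 2) and
#'   \code{nItems} (total ids covered).
#' @examples
#' rel <- data.frame(geneA = c("A", "B", "D"), geneB = c("B", "C", "E"))
#' transitiveClosure(rel)$components
#' @export
transitiveClosure <- function(relations) {
  stopifnot(is.data.frame(relations),
            all(c("geneA", "geneB") %in% names(relations)))
  if (nrow(relations) == 0L)
    return(structure(list(components = list(), nItems = 0L),
                     class = "ClusterPartition"))
  g <- igraph::graph_from_data_frame(
    relations[, c("geneA", "geneB")], directed = FALSE)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort)
  comps <- unname(comps[order(vapply(comps, `[[`, "", 1L))])
  structure(list(components = comps,
                 nItems = as.integer(sum(lengths(comps)))),
            class = "ClusterPartition")
}

#' @export
print.ClusterPartition <- function(x, ...) {
  cat("ClusterPartition: ", length(x$components), " clusters over ",
      x$nItems, " genes\n", sep = "")
  invisible(x)
}

#' Number of pairwise comparisons among proteomes
#'
#' All-against-all pairwise orthology prediction over \eqn{N} proteomes
#' requires \eqn{N(N-1)/2} runs.
#'
#' @param nProteomes integer >= 2.
#' @return \code{nProteomes * (nProteomes - 1) / 2}.
#' @examples
#' pairCount(20)  # 190
#' @export
pairCount <- function(nProteomes) {
  stopifnot(is.numeric(nProteomes), length(nProteomes) == 1L)
  if (nProteomes < 2) stop("need at least 2 proteomes")
  as.integer(nProteomes * (nProteomes - 1) / 2)
}

#' Write cluster membership of a partition as TSV
#'
#' @param partition a [transitiveClosure()] result.
#' @param path output path; columns \code{clusterId}, \code{geneId}.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(partition, path) {
  stopifnot(inherits(partition, "ClusterPartition"))
  df <- data.frame(
    clusterId = rep(sprintf("cluster_%05d", seq_along(partition$components)),
                    lengths(partition$components)),
    geneId = unlist(partition$components, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract per-cluster sequence sets from a proteome
#'
#' @param partition a [transitiveClosure()] result.
#' @param proteome named \code{AAStringSet} holding all gene sequences.
#' @return List of [HomologyCluster-class] objects (components whose
#'   members are missing from the proteome raise an error naming them).
#' @export
partitionClusters <- function(partition, proteome) {
  stopifnot(inherits(partition, "ClusterPartition"),
            methods::is(proteome, "XStringSet"))
  lapply(seq_along(partition$components), function(i) {
    ids <- partition$components[[i]]
    missing <- setdiff(ids, names(proteome))
    if (length(missing))
      stop("gene(s) absent from proteome: ",
           paste(missing, collapse = ", "))
    HomologyCluster(proteome[ids],
                    clusterId = sprintf("cluster_%05d", i))
  })
}
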