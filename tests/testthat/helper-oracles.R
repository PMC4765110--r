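## Fixture builders and independent brute-force oracles used across tests.

AAs <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomProtein <- function(len, alphabet = AAs) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

randomCluster <- function(n = 3L, lenRange = c(20L, 40L), id = "fix") {
  lens <- sample(seq(lenRange[1L], lenRange[2L]), n, replace = TRUE)
  seqs <- vapply(lens, randomProtein, "")
  names(seqs) <- paste0(id, "_s", seq_len(n))
  HomologyCluster(seqs, clusterId = id)
}

## Exhaustive optimal global affine-gap alignment score: enumerate every
## monotone alignment path and score maximal gap runs as
## open + (k - 1) * ext.  Feasible for sequences of length <= 6.
bruteAlignScore <- function(a, b, mat, open, ext) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  scoreMoves <- function(moves) {
    i <- 0L; j <- 0L; s <- 0
    r <- rle(moves)
    for (k in seq_along(r$values)) {
      v <- r$values[k]; n <- r$lengths[k]
      if (v == "D") {
        for (q in seq_len(n)) {
          i <- i + 1L; j <- j + 1L
          s <- s + mat[ac[i], bc[j]]
        }
      } else {
        s <- s + open + (n - 1) * ext
        if (v == "U") i <- i + n else j <- j + n
      }
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i == length(ac) && j == length(bc)) {
      best <<- max(best, scoreMoves(moves))
      return(invisible(NULL))
    }
    if (i < length(ac) && j < length(bc)) rec(i + 1L, j + 1L, c(moves, "D"))
    if (i < length(ac)) rec(i + 1L, j, c(moves, "U"))
    if (j < length(bc)) rec(i, j + 1L, c(moves, "L"))
  }
  rec(0L, 0L, character())
  best
}

## Transitive closure by repeated relational join until fixpoint.
bruteClosure <- function(relations) {
  sets <- lapply(seq_len(nrow(relations)), function(i)
    c(relations$geneA[i], relations$geneB[i]))
  repeat {
    changed <- FALSE
    k <- 1L
    while (k < length(sets)) {
      merged <- FALSE
      for (m in seq(k + 1L, length(sets))) {
        if (length(intersect(sets[[k]], sets[[m]]))) {
          sets[[k]] <- union(sets[[k]], sets[[m]])
          sets[[m]] <- NULL
          changed <- TRUE; merged <- TRUE
          break
        }
      }
      if (!merged) k <- k + 1L
    }
    if (!changed) break
  }
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[[`, "", 1L))]
}

## a small linearly separable two-class feature table
separableTable <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  half <- n %/% 2L
  data.frame(
    label = rep(c("H", "NH"), each = half),
    f1 = c(rnorm(half, 0), rnorm(half, 8)),
    f2 = c(rnorm(half, 0), rnorm(half, -8)),
    stringsAsFactors = FALSE)
}

digest_file <- function(path) unname(tools::md5sum(path))

b62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
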