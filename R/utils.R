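## Internal helpers shared across modules.

#' Derive a stage-scoped random seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its RNG stream from the
#' master seed plus a stage name, so that one integer reproduces a whole
#' run while stages remain statistically independent.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. \code{"simulate"}).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @examples
#' deriveSeed(1L, "simulate")
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(as.numeric(master)) * 69069 + h) %% 2147483647)
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG
## state.  `seed = NA` runs on the ambient stream.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## The 20 standard amino acids, PAM/WAG ordering (PAML convention).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Characters legal in cluster FASTA input (after uppercasing).
LEGAL_RESIDUES <- c(AA20, "X", "-")

CLUSTER_LABELS <- c("H", "NH", "UNKNOWN")
CLUSTER_PROVENANCES <- c("REAL", "NH_RANDOM", "NH_EVOLVED_0", "NH_EVOLVED_25",
                         "NH_EVOLVED_50", "H_SYNTH")

## Alignment (or sequence set) as a character matrix, rows = sequences.
asResidueMatrix <- function(x) {
  stopifnot(methods::is(x, "XStringSet"))
  wd <- unique(Biostrings::width(x))
  stopifnot(length(wd) == 1L)
  m <- matrix(unlist(strsplit(as.character(x), "", fixed = TRUE), use.names = FALSE),
              nrow = length(x), ncol = wd, byrow = TRUE)
  rownames(m) <- names(x)
  m
}

degap <- function(x) {
  Biostrings::AAStringSet(gsub("-", "", as.character(x), fixed = TRUE))
}
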