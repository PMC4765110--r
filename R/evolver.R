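## evolver: generative construction of ground-truth training clusters.
##
## Non-homology decoys arise two ways: random draws from the protein pool
## (cluster size ~ Poisson), and deep simulated divergence of real cluster
## members on random binary trees under WAG+I. A synthetic homology
## generator provides low-divergence protein families for self-contained
## operation.

#' Random-tree parameters
#'
#' @param tipMean mean of the Normal distribution the (discretised) tip
#'   count is drawn from (default 50).
#' @param tipSD its standard deviation (default 15).
#' @param branchLengthMean mean of the i.i.d. Exponential branch lengths,
#'   in substitutions per site (default 0.5; the trees must diverge tips
#'   far enough to break homology signal).
#' @param seed integer seed (\code{NA} uses the ambient stream).
#' @return A validated list of class \code{TreeParams}.
#' @examples
#' treeParams()$tipMean
#' @export
treeParams <- function(tipMean = 50, tipSD = 15, branchLengthMean = 0.5,
                       seed = NA_integer_) {
  stopifnot(tipMean > 2, tipSD > 0, branchLengthMean > 0)
  structure(list(tipMean = tipMean, tipSD = tipSD,
                 branchLengthMean = branchLengthMean, seed = seed),
            class = "TreeParams")
}

#' Non-homology random-draw parameters
#'
#' @param poissonLambda Poisson mean for cluster sizes (default 44.3056,
#'   the average homology-cluster size the generative construction is
#'   calibrated to).
#' @param minClusterSize smallest admissible cluster (default 2); smaller
#'   Poisson draws are redrawn.
#' @param seed integer seed.
#' @return A validated list of class \code{NHGenParams}.
#' @export
nhGenParams <- function(poissonLambda = 44.3056, minClusterSize = 2L,
                        seed = NA_integer_) {
  stopifnot(poissonLambda > 0, minClusterSize >= 2L)
  structure(list(poissonLambda = poissonLambda,
                 minClusterSize = as.integer(minClusterSize), seed = seed),
            class = "NHGenParams")
}

#' Sample cluster sizes from the (optionally truncated) Poisson
#'
#' @param n number of draws.
#' @param lambda Poisson mean (default 44.3056).
#' @param minSize redraw values below this (default 2).
#' @param maxSize redraw values above this (default unbounded).
#' @param truncate disable to sample the plain Poisson (used e.g. to check
#'   the sampler's mean against its nominal value).
#' @param seed integer seed.
#' @return Integer vector of length \code{n}.
#' @examples
#' mean(sampleClusterSize(1000, seed = 1))
#' @export
sampleClusterSize <- function(n, lambda = 44.3056, minSize = 2L,
                              maxSize = Inf, truncate = TRUE,
                              seed = NA_integer_) {
  withLocalSeed(seed, {
    out <- stats::rpois(n, lambda)
    if (truncate) {
      bad <- out < minSize | out > maxSize
      while (any(bad)) {
        out[bad] <- stats::rpois(sum(bad), lambda)
        bad <- out < minSize | out > maxSize
      }
    }
    out
  })
}

#' Sample a random binary tree
#'
#' Tip count = a Normal(\code{tipMean}, \code{tipSD}) draw rounded to an
#' integer, redrawn until >= 2; topology by random sequential coalescence;
#' branch lengths i.i.d. Exponential with mean \code{branchLengthMean}.
#'
#' @param params a [treeParams()].
#' @return An \code{ape} \code{phylo} object with positive edge lengths.
#' @examples
#' tr <- sampleTree(treeParams(seed = 1))
#' ape::Ntip(tr)
#' @export
sampleTree <- function(params = treeParams()) {
  withLocalSeed(params$seed, {
    repeat {
      n <- round(stats::rnorm(1, params$tipMean, params$tipSD))
      if (n >= 2) break
    }
    tr <- ape::rcoal(n)
    tr$edge.length <- stats::rexp(nrow(tr$edge),
                                  rate = 1 / params$branchLengthMean)
    tr
  })
}

encodeAA <- function(chars) {
  x <- match(strsplit(chars, "")[[1L]], AA20)
  if (anyNA(x))
    stop("sequence contains residues outside the 20 standard amino acids ",
         "(e.g. 'X'); cannot evolve unknown residues")
  x
}

decodeAA <- function(x) paste(AA20[x], collapse = "")

## substitute variable sites of an integer-encoded sequence under P
mutateSites <- function(seqInt, P, variable) {
  out <- seqInt
  res <- seqInt[variable]
  for (r in unique(res)) {
    at <- variable[res == r]
    out[at] <- sample.int(20L, length(at), replace = TRUE, prob = P[r, ])
  }
  out
}

#' Evolve a root sequence over a tree under WAG+I
#'
#' Continuous-time Markov substitution per site along every edge (exact
#' transition matrices from the model eigendecomposition). A fraction
#' \code{model$pInv} of sites, chosen once per root as an exact-count
#' mask, never mutates anywhere in the tree — so at \code{pInv = 0.5} at
#' least half of all columns are identical across tips by construction.
#' The process has no indels: every tip has the root's length.
#'
#' @param root ungapped amino-acid sequence (character scalar,
#'   \code{AAString}, or length-1 \code{AAStringSet}); must not contain
#'   \code{X}.
#' @param tree a \code{phylo} from [sampleTree()].
#' @param model a [wagModel()].
#' @param seed integer seed.
#' @return \code{AAStringSet} of tip sequences, named by tip label.
#' @examples
#' tips <- evolveOnTree("MKLVDEWQRAGH", sampleTree(treeParams(seed = 2)),
#'                      wagModel(0.5), seed = 3)
#' unique(Biostrings::width(tips))
#' @export
evolveOnTree <- function(root, tree, model, seed = NA_integer_) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "EvolutionModel"))
  rootChars <- toupper(as.character(root))
  rootInt <- encodeAA(rootChars)
  L <- length(rootInt)
  tree <- stats::reorder(tree, "cladewise")  # preorder edge traversal
  withLocalSeed(seed, {
    variable <- invariantMaskComplement(L, model$pInv)
    nTip <- length(tree$tip.label)
    seqs <- vector("list", nTip + tree$Nnode)
    rootNode <- nTip + 1L
    seqs[[rootNode]] <- rootInt
    ord <- seq_len(nrow(tree$edge))
    Pcache <- new.env(parent = emptyenv())
    for (e in ord) {
      parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      t <- tree$edge.length[e]
      key <- format(t, digits = 17)
      P <- Pcache[[key]]
      if (is.null(P)) {
        P <- transitionMatrix(model, t)
        Pcache[[key]] <- P
      }
      seqs[[child]] <- mutateSites(seqs[[parent]], P, variable)
    }
    out <- Biostrings::AAStringSet(vapply(seqs[seq_len(nTip)], decodeAA, ""))
    names(out) <- tree$tip.label
    out
  })
}

## indices of sites allowed to vary (complement of the invariable mask)
invariantMaskComplement <- function(L, pInv) {
  nInv <- round(pInv * L)
  if (nInv == 0) return(seq_len(L))
  if (nInv >= L) return(integer(0))
  setdiff(seq_len(L), sample.int(L, nInv))
}

#' Build a non-homology cluster by evolving a homology cluster's members
#'
#' Per member: sample a random binary tree, evolve the member over it
#' under WAG+I, and keep one randomly chosen tip. The picks are aligned
#' and labelled NH with provenance \code{NH_EVOLVED_\{0|25|50\}} by the
#' model's invariable-site proportion.
#'
#' With \code{collapse = TRUE} (default) the chosen tip is drawn first and
#' the member evolved along its root-to-tip path length in a single exact
#' step — the Markov property makes this distributionally identical to
#' evolving the whole tree and then picking, at a fraction of the cost.
#' \code{collapse = FALSE} runs the literal full-tree route.
#'
#' @param h a [HomologyCluster-class] with ungapped members free of
#'   \code{X}.
#' @param model a [wagModel()] at the desired invariable-site proportion.
#' @param tparams a [treeParams()].
#' @param seed integer seed.
#' @param alnParams an [alignParams()] for aligning the picks.
#' @param collapse see Details.
#' @return An aligned NH [HomologyCluster-class] with as many members as
#'   \code{h}; member lengths equal the input lengths (substitution-only
#'   evolution).
#' @export
makeNHEvolved <- function(h, model, tparams = treeParams(),
                          seed = NA_integer_, alnParams = alignParams(),
                          collapse = TRUE) {
  stopifnot(methods::is(h, "HomologyCluster"),
            inherits(model, "EvolutionModel"))
  prov <- sprintf("NH_EVOLVED_%d", as.integer(round(model$pInv * 100)))
  if (!prov %in% CLUSTER_PROVENANCES)
    prov <- "NH_EVOLVED_0"
  mem <- members(h)
  picks <- withLocalSeed(seed, {
    out <- character(length(mem))
    for (k in seq_along(mem)) {
      tp <- tparams; tp$seed <- NA_integer_
      tr <- sampleTree(tp)
      tip <- sample.int(length(tr$tip.label), 1L)
      if (collapse) {
        depth <- ape::node.depth.edgelength(tr)[tip]
        rootInt <- encodeAA(as.character(mem[[k]]))
        variable <- invariantMaskComplement(length(rootInt), model$pInv)
        P <- transitionMatrix(model, depth)
        out[k] <- decodeAA(mutateSites(rootInt, P, variable))
      } else {
        tips <- evolveOnTree(as.character(mem[[k]]), tr, model)
        out[k] <- as.character(tips[[tip]])
      }
    }
    names(out) <- paste0(names(mem), "_ev")
    out
  })
  cl <- HomologyCluster(picks,
                        clusterId = paste0(clusterId(h), "_", tolower(prov)),
                        label = "NH", provenance = prov)
  progressiveAlign(cl, alnParams)
}

#' Build a non-homology cluster by random draws from a protein pool
#'
#' Cluster size ~ Poisson(\code{poissonLambda}) (redrawn until it fits
#' \code{[minClusterSize, pool size]}); members drawn uniformly without
#' replacement from the totality of pool sequences; aligned; labelled NH
#' with provenance \code{NH_RANDOM}.
#'
#' @param pool named \code{AAStringSet} of candidate sequences.
#' @param params an [nhGenParams()].
#' @param clusterId id for the new cluster.
#' @param alnParams an [alignParams()].
#' @return An aligned NH [HomologyCluster-class].
#' @export
makeNHRandom <- function(pool, params = nhGenParams(),
                         clusterId = "nh_random",
                         alnParams = alignParams()) {
  stopifnot(methods::is(pool, "XStringSet"))
  if (length(pool) < params$minClusterSize)
    stop("pool of ", length(pool), " sequences is smaller than the ",
         "minimum cluster size ", params$minClusterSize)
  cl <- withLocalSeed(params$seed, {
    s <- sampleClusterSize(1L, params$poissonLambda,
                           minSize = params$minClusterSize,
                           maxSize = length(pool))
    take <- sample.int(length(pool), s)
    HomologyCluster(pool[take], clusterId = clusterId, label = "NH",
                    provenance = "NH_RANDOM")
  })
  progressiveAlign(cl, alnParams)
}

#' Generate synthetic homology clusters
#'
#' Desk-scale stand-in for curated single-copy ortholog families: each
#' cluster is the tip set of a single shallow random tree evolved from one
#' random root (drawn from WAG equilibrium frequencies) under WAG at a
#' small divergence, so members are conserved, equal-length and gap-poor —
#' the qualitative signature of true homology clusters. Labelled H with
#' provenance \code{H_SYNTH}.
#'
#' @param nClusters number of clusters to generate.
#' @param sizeLambda Poisson mean for cluster sizes (default 44.3056).
#' @param rootLengthRange integer range root lengths are drawn uniformly
#'   from (default 120-400 aa, typical protein lengths).
#' @param divergence mean branch length in substitutions/site (default
#'   0.05; must stay well below the non-homology branch scale so homologs
#'   remain more conserved than decoys).
#' @param seed integer seed.
#' @param alnParams an [alignParams()].
#' @param align align each cluster (default TRUE).
#' @return List of H [HomologyCluster-class] objects.
#' @examples
#' hs <- makeHSynthetic(2, sizeLambda = 5, rootLengthRange = c(40, 60),
#'                      seed = 1)
#' provenance(hs[[1]])
#' @export
makeHSynthetic <- function(nClusters, sizeLambda = 44.3056,
                           rootLengthRange = c(120L, 400L),
                           divergence = 0.05, seed = NA_integer_,
                           alnParams = alignParams(), align = TRUE) {
  stopifnot(nClusters >= 1L, divergence > 0,
            length(rootLengthRange) == 2L,
            rootLengthRange[1L] >= 1L,
            rootLengthRange[1L] <= rootLengthRange[2L])
  model <- wagModel(0)
  withLocalSeed(seed, {
    lapply(seq_len(nClusters), function(i) {
      s <- sampleClusterSize(1L, sizeLambda)
      L <- sample(seq(rootLengthRange[1L], rootLengthRange[2L]), 1L)
      root <- decodeAA(sample.int(20L, L, replace = TRUE,
                                  prob = wagFrequencies()))
      tr <- ape::rcoal(s)
      tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / divergence)
      tips <- evolveOnTree(root, tr, model)
      names(tips) <- sprintf("h%04d_s%03d", i, seq_along(tips))
      cl <- HomologyCluster(tips, clusterId = sprintf("h_synth_%04d", i),
                            label = "H", provenance = "H_SYNTH")
      if (align) progressiveAlign(cl, alnParams) else cl
    })
  })
}
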