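test_that("the WAG rate matrix satisfies its structural identities", {
  m <- wagModel(0)
  expect_equal(sum(m$freqs), 1, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(m$Q))), 1e-10)
  # detailed balance pi_i q_ij = pi_j q_ji
  M <- m$freqs * m$Q
  expect_lt(max(abs(M - t(M))), 1e-10)
  # unit expected substitution rate
  expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)
})

test_that("embedded WAG constants agree with an independent copy", {
  skip_if_not_installed("phangorn")
  ref <- get(".WAG", envir = asNamespace("phangorn"))
  S <- OrthoSieve:::wagExchangeabilities()
  expect_equal(unname(S[lower.tri(S)]), ref$Q, tolerance = 1e-12)
  expect_equal(unname(OrthoSieve:::wagFrequencies()), unname(ref$bf),
               tolerance = 1e-6)
})

test_that("transition matrices behave at the limits", {
  m <- wagModel(0)
  expect_equal(transitionMatrix(m, 0), diag(20),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(rowSums(transitionMatrix(m, 1.7))), rep(1, 20))
  # long branches converge to the equilibrium frequencies row-wise
  P <- transitionMatrix(m, 50)
  expect_lt(max(abs(sweep(P, 2, m$freqs))), 1e-8)
})

test_that("random trees have the right shape and determinism", {
  tr <- sampleTree(treeParams(seed = 1))
  n <- ape::Ntip(tr)
  expect_gte(n, 2)
  expect_equal(tr$Nnode, n - 1)          # rooted binary: n-1 internal nodes
  expect_equal(nrow(tr$edge), 2 * (n - 1))
  expect_true(all(tr$edge.length > 0))
  expect_equal(sampleTree(treeParams(seed = 5)),
               sampleTree(treeParams(seed = 5)))
})

test_that("tree tip counts track the Normal(50, 15) target", {
  n <- vapply(1:400, function(k)
    ape::Ntip(sampleTree(treeParams(seed = k))), 0)
  se <- 15 / sqrt(length(n))
  expect_lt(abs(mean(n) - 50), 3 * se + 0.1)
})

test_that("evolution is substitution-only and honors limiting cases", {
  root <- randomProtein(80)
  tr <- sampleTree(treeParams(seed = 3))
  tips <- evolveOnTree(root, tr, wagModel(0), seed = 4)
  expect_equal(length(tips), ape::Ntip(tr))
  expect_equal(unique(Biostrings::width(tips)), nchar(root))
  # p_inv = 1: nothing may change anywhere
  tipsInv <- evolveOnTree(root, tr, wagModel(1), seed = 4)
  expect_true(all(as.character(tipsInv) == root))
  # X cannot be evolved
  expect_error(evolveOnTree("MKXLV", tr, wagModel(0), seed = 1), "X")
})

test_that("half-invariable evolution keeps >= half of columns identical", {
  root <- randomProtein(400)
  tr <- sampleTree(treeParams(seed = 6))
  tips <- evolveOnTree(root, tr, wagModel(0.5), seed = 7)
  mat <- vapply(as.character(tips), function(s) strsplit(s, "")[[1]],
                character(nchar(root)))
  identical_cols <- sum(apply(mat, 1, function(r) length(unique(r)) == 1))
  expect_gte(identical_cols / nchar(root), 0.5)
})

test_that("long-branch tips approach the WAG equilibrium composition", {
  m <- wagModel(0)
  tr <- ape::rcoal(2)
  tr$edge.length <- c(10, 10)
  tips <- evolveOnTree(paste(rep("A", 10000), collapse = ""), tr, m,
                       seed = 8)
  f <- as.numeric(Biostrings::letterFrequency(tips[1], AAs)) / 10000
  expect_lt(0.5 * sum(abs(f - unname(m$freqs))), 0.05)
})

test_that("Poisson cluster sizes center on lambda and respect truncation", {
  x <- sampleClusterSize(20000, lambda = 44.3056, truncate = FALSE,
                         seed = 9)
  se <- sqrt(44.3056 / length(x))
  expect_lt(abs(mean(x) - 44.3056), 3 * se)
  y <- sampleClusterSize(500, lambda = 2, minSize = 2, seed = 10)
  expect_true(all(y >= 2))
})

test_that("evolved NH clusters preserve size and lengths but lose identity", {
  hs <- makeHSynthetic(3, sizeLambda = 6, rootLengthRange = c(60L, 90L),
                       seed = 11)
  pid <- function(cl) {
    s <- as.character(members(cl))
    n <- length(s)
    tot <- 0; cnt <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (nchar(s[i]) == nchar(s[j])) {
        a <- strsplit(s[i], "")[[1]]; b <- strsplit(s[j], "")[[1]]
        tot <- tot + mean(a == b); cnt <- cnt + 1
      }
    }
    if (cnt) tot / cnt else NA_real_
  }
  for (k in seq_along(hs)) {
    nh <- makeNHEvolved(hs[[k]], wagModel(0), treeParams(), seed = 20 + k)
    expect_equal(nSequences(nh), nSequences(hs[[k]]))
    expect_equal(sort(Biostrings::width(members(nh))),
                 sort(Biostrings::width(members(hs[[k]]))))
    expect_equal(provenance(nh), "NH_EVOLVED_0")
    expect_equal(clusterLabel(nh), "NH")
    expect_lt(pid(nh), pid(hs[[k]]))
  }
})

test_that("collapsed and full-tree evolved decoys share the contract", {
  hs <- makeHSynthetic(1, sizeLambda = 4, rootLengthRange = c(40L, 50L),
                       seed = 31)
  full <- makeNHEvolved(hs[[1]], wagModel(0.25), treeParams(), seed = 32,
                        collapse = FALSE)
  expect_equal(nSequences(full), nSequences(hs[[1]]))
  expect_equal(provenance(full), "NH_EVOLVED_25")
})

test_that("random-draw NH clusters sample without replacement, reproducibly", {
  pool <- Biostrings::AAStringSet(vapply(1:80, function(i)
    randomProtein(sample(30:60, 1)), ""))
  names(pool) <- paste0("p", 1:80)
  p <- nhGenParams(poissonLambda = 10, seed = 41)
  cl1 <- makeNHRandom(pool, p)
  cl2 <- makeNHRandom(pool, p)
  expect_false(anyDuplicated(names(members(cl1))) > 0)
  expect_equal(names(members(cl1)), names(members(cl2)))
  expect_equal(clusterLabel(cl1), "NH")
  expect_equal(provenance(cl1), "NH_RANDOM")
  expect_error(makeNHRandom(pool[1], nhGenParams()), "smaller")
})

test_that("synthetic homologs are conserved, equal-length families", {
  hs <- makeHSynthetic(3, sizeLambda = 5, rootLengthRange = c(50L, 70L),
                       seed = 51)
  expect_length(hs, 3)
  for (h in hs) {
    expect_equal(length(unique(Biostrings::width(members(h)))), 1L)
    expect_equal(clusterLabel(h), "H")
    expect_equal(provenance(h), "H_SYNTH")
  }
  # homologs must be more self-similar than their evolved decoys
  nh <- makeNHEvolved(hs[[1]], wagModel(0), treeParams(), seed = 52)
  colId <- function(cl) {
    m <- vapply(as.character(members(cl)),
                function(s) strsplit(s, "")[[1]],
                character(nchar(as.character(members(cl))[1])))
    mean(apply(m, 1, function(r) length(unique(r)) == 1))
  }
  expect_gt(colId(hs[[1]]), colId(nh))
})
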