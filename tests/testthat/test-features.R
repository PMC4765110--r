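alnOf <- function(...) Biostrings::AAStringSet(c(...))

test_that("gap and residue counts are exact and complementary", {
  expect_equal(countGaps(alnOf(a = "AC-", b = "A--")), 3)
  expect_equal(countAminoAcids(alnOf(a = "AC-", b = "A--")), 3)
  expect_equal(countGaps(alnOf(a = "ACD", b = "AAD")), 0)
  expect_equal(countAminoAcids(alnOf(a = "A", b = "-")), 1)
  set.seed(31)
  for (rep in 1:20) {
    cl <- progressiveAlign(randomCluster(sample(2:5, 1)))
    aln <- alignment(cl)
    expect_equal(countGaps(aln) + countAminoAcids(aln),
                 length(aln) * Biostrings::width(aln)[1])
  }
  # adding an all-gap row of length L adds exactly L gaps
  aln <- alnOf(a = "ACD", b = "AAD")
  aug <- alnOf(a = "ACD", b = "AAD", c = "---")
  expect_equal(countGaps(aug), countGaps(aln) + 3)
})

test_that("sequence range is max minus min ungapped length", {
  cl <- HomologyCluster(c(a = randomProtein(10), b = randomProtein(7),
                          c = randomProtein(9)))
  expect_equal(sequenceRange(cl), 3L)
  cl2 <- HomologyCluster(c(a = "MKLV", b = "MKIV"))
  expect_equal(sequenceRange(cl2), 0L)
  set.seed(41)
  for (rep in 1:100) {
    cl <- randomCluster(sample(2:6, 1), lenRange = c(5L, 50L))
    w <- nchar(as.character(members(cl)))
    expect_equal(sequenceRange(cl), max(w) - min(w))
  }
})

test_that("class dispersion matches hand and two-pass oracle values", {
  # p = {1, 0} for charged -> Bessel variance 0.5, sd sqrt(0.5)
  expect_equal(classDispersion(alnOf(a = "DE", b = "AA"), cls = "charged"),
               sqrt(0.5), tolerance = 1e-6)
  # identical rows -> zero dispersion in every class
  same <- alnOf(a = "MKDEC", b = "MKDEC", c = "MKDEC")
  for (cls in c("charged", "uncharged", "hydrophobic", "special"))
    expect_equal(classDispersion(same, cls = cls), 0)
  # two-pass variance oracle on random alignments
  sch <- aminoClassScheme()
  set.seed(51)
  for (rep in 1:100) {
    cl <- progressiveAlign(randomCluster(sample(2:5, 1),
                                         lenRange = c(8L, 20L)))
    aln <- alignment(cl)
    p <- vapply(seq_along(aln), function(i) {
      ch <- strsplit(as.character(aln[[i]]), "")[[1]]
      ch <- ch[ch != "-" & ch != "X"]
      sum(ch %in% sch$charged) / length(ch)
    }, 0)
    expect_equal(classDispersion(aln, sch, "charged"),
                 sqrt(sum((p - mean(p))^2) / (length(p) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("a row without countable residues errors with its id", {
  aln <- alnOf(good = "MKDE", allx = "XX--")
  expect_error(classDispersion(aln, cls = "charged"), "allx")
})

test_that("per-row class proportions always sum to one", {
  set.seed(61)
  for (rep in 1:10) {
    aln <- alignment(progressiveAlign(randomCluster(3)))
    p <- OrthoSieve:::classProportions(aln)
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)))
  }
})

test_that("the scheme must partition the 20 residues", {
  expect_error(aminoClassScheme(charged = c("D", "E")), "cover")
  expect_error(aminoClassScheme(charged = c("D", "E", "K", "R", "H", "S")),
               "disjoint")
})

test_that("the feature vector has exactly the ten named attributes", {
  cl <- progressiveAlign(randomCluster(3))
  fv <- clusterFeatures(cl, rparams = randomnessParams(seed = 1))
  expect_named(fv, c("aliscore", "length", "n_sequences", "n_gaps",
                     "n_amino_acids", "range", "sd_charged",
                     "sd_uncharged", "sd_special", "sd_hydrophobic"))
  expect_true(all(fv[c("sd_charged", "sd_uncharged", "sd_special",
                       "sd_hydrophobic")] >= 0))
  expect_true(fv["aliscore"] >= 0 && fv["aliscore"] <= fv["length"])
})

test_that("identical members give zero gaps, range and dispersion", {
  s <- randomProtein(30)
  cl <- progressiveAlign(HomologyCluster(c(a = s, b = s)))
  fv <- clusterFeatures(cl, rparams = randomnessParams(seed = 2))
  expect_equal(unname(fv["n_gaps"]), 0)
  expect_equal(unname(fv["range"]), 0)
  expect_equal(unname(fv[c("sd_charged", "sd_uncharged", "sd_special",
                           "sd_hydrophobic")]), rep(0, 4))
})

test_that("features are invariant to row permutation", {
  set.seed(71)
  cl <- progressiveAlign(randomCluster(5, lenRange = c(15L, 25L)))
  perm <- sample(nSequences(cl))
  clP <- HomologyCluster(members(cl)[perm], clusterId = clusterId(cl),
                         alignment = alignment(cl)[perm])
  rp <- randomnessParams(seed = 9)
  expect_equal(clusterFeatures(cl, rparams = rp),
               clusterFeatures(clP, rparams = rp))
})

test_that("class dispersion is invariant to duplicating columns", {
  aln <- alnOf(a = "MKDEC", b = "MADEC", c = "MKDGC")
  dup <- Biostrings::AAStringSet(paste0(as.character(aln),
                                        as.character(aln)))
  names(dup) <- names(aln)
  for (cls in c("charged", "uncharged", "hydrophobic", "special"))
    expect_equal(classDispersion(aln, cls = cls),
                 classDispersion(dup, cls = cls))
})

test_that("a precomputed randomness value overrides the internal scorer", {
  cl <- progressiveAlign(randomCluster(3, lenRange = c(20L, 20L)))
  cl <- attachAliscore(cl, 12)
  fv <- clusterFeatures(cl, rparams = randomnessParams(seed = 1))
  expect_equal(unname(fv["aliscore"]), 12)
  expect_error(attachAliscore(cl, Biostrings::width(alignment(cl))[1] + 1),
               "must lie in")
})

test_that("featurizeClusters aligns on demand and labels rows", {
  cls <- list(HomologyCluster(c(a = "MKLVW", b = "MKLW"), clusterId = "u1"),
              progressiveAlign(randomCluster(3, id = "u2")))
  tbl <- featurizeClusters(cls, rparams = randomnessParams(seed = 4))
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$clusterId, c("u1", "u2"))
  expect_true(all(c("label", "provenance") %in% names(tbl)))
})
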