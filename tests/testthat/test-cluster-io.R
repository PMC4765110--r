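test_that("aligned input is detected and degapped members recovered", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK-LV", ">b", "MKQLV"), tf)
  cl <- readClusterFasta(tf)
  expect_true(hasAlignment(cl))
  expect_equal(nSequences(cl), 2L)
  expect_equal(as.character(members(cl)),
               c(a = "MKLV", b = "MKQLV"))
  expect_equal(clusterLabel(cl), "UNKNOWN")
})

test_that("equal-length gap-free input stays unaligned unless forced", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKLV", ">b", "MKQV", ">c", "MKCV"), tf)
  expect_false(hasAlignment(readClusterFasta(tf)))
  expect_true(hasAlignment(readClusterFasta(tf, aligned = TRUE)))
})

test_that("unequal-length ungapped input yields an unaligned cluster", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKLVW", ">b", "MKV", ">c", "MKLV"), tf)
  cl <- readClusterFasta(tf)
  expect_false(hasAlignment(cl))
  expect_equal(nSequences(cl), 3L)
})

test_that("degenerate and malformed inputs error informatively", {
  one <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">only", "MKLV"), one)
  expect_error(readClusterFasta(one), "fewer than 2")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "MKLV", ">oops", "MK7LV"), bad)
  expect_error(readClusterFasta(bad), "oops")

  stops <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKLV*", ">b", "MKIV"), stops)
  expect_warning(cl <- readClusterFasta(stops), "stop codons")
  expect_equal(as.character(members(cl))[["a"]], "MKLV")
})

test_that("lowercase input is stored uppercase", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "mklv", ">b", "mkiv"), tf)
  expect_equal(as.character(members(readClusterFasta(tf))),
               c(a = "MKLV", b = "MKIV"))
})

test_that("write/read round-trip preserves ids and residues", {
  set.seed(7)
  for (rep in 1:5) {
    cl <- randomCluster(n = sample(2:6, 1), id = paste0("rt", rep))
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeClusterFasta(cl, tf)
    back <- readClusterFasta(tf)
    expect_equal(as.character(members(back)), as.character(members(cl)))
  }
  cl <- progressiveAlign(randomCluster(4, id = "rtA"))
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeClusterFasta(cl, tf, aligned = TRUE)
  back <- readClusterFasta(tf)
  expect_true(hasAlignment(back) || countGaps(alignment(cl)) == 0)
  expect_equal(sort(as.character(members(back))),
               sort(as.character(members(cl))))
})

test_that("writing aligned FASTA without an alignment is a state error", {
  cl <- HomologyCluster(c(a = "MKL", b = "MKI"))
  expect_error(writeClusterFasta(cl, tempfile(), aligned = TRUE),
               "no alignment")
})

test_that("relations are deduplicated, symmetric and self-pair free", {
  tf <- withr::local_tempfile()
  writeLines(c("A\tB", "B\tA", "A\tB", "# comment", "B\tC"), tf)
  rel <- readRelations(tf)
  expect_equal(nrow(rel), 2L)
  expect_setequal(paste(rel$geneA, rel$geneB), c("A B", "B C"))

  selfs <- withr::local_tempfile()
  writeLines("A\tA", selfs)
  expect_warning(rel2 <- readRelations(selfs), "self-pair")
  expect_equal(nrow(rel2), 0L)

  bad <- withr::local_tempfile()
  writeLines(c("A\tB", "A B C"), bad)
  expect_error(readRelations(bad), "line 2")
})

test_that("relation reading is invariant to line order", {
  lines <- c("A B", "C D", "B C", "E F", "D A")
  f1 <- withr::local_tempfile(); writeLines(lines, f1)
  f2 <- withr::local_tempfile(); writeLines(rev(lines), f2)
  r1 <- readRelations(f1); r2 <- readRelations(f2)
  key <- function(r) sort(paste(r$geneA, r$geneB))
  expect_equal(key(r1), key(r2))
})

test_that("cluster validity rejects inconsistent alignments", {
  expect_error(HomologyCluster(c(a = "MKL")), "at least 2")
  expect_error(
    HomologyCluster(c(a = "MKL", b = "MKI"),
                    alignment = c(a = "M-KL", b = "MKIV")),
    "degapped")
})
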