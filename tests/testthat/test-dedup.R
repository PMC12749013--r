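test_that("the three comparators implement their duplicate definitions", {
  # tight: full-length equality only
  expect_true(compareTight("ACGT", "ACGT"))
  expect_true(compareTight("acgt", "ACGT"))
  expect_false(compareTight("ACGT", "ACGTA"))   # length mismatch
  expect_false(compareTight("ACGT", "ACGA"))
  # loose: shorter is a prefix of longer
  expect_true(compareLoose("ACGT", "ACGTAA"))
  expect_true(compareLoose("ACGTAA", "ACGT"))   # symmetric
  expect_true(compareLoose("ACGT", "ACGT"))
  expect_false(compareLoose("ACGA", "ACGT"))
  expect_true(compareLoose("", "ACGT"))         # empty is everyone's prefix
  # tail-hamming: bounded mismatches at equal length
  expect_true(compareTailHamming("ACGT", "ACGA", 1))
  expect_true(compareTailHamming("ACGT", "ACGT", 0))
  expect_false(compareTailHamming("AAAA", "TTTT", 2))  # distance 4
  expect_false(compareTailHamming("ACGT", "ACGTA", 99))  # length rule
  # vectorized
  expect_equal(compareLoose(c("A", "C"), c("AT", "AT")), c(TRUE, FALSE))
  expect_equal(hammingDistance(c("AAAA", "AAC"), c("ATAA", "AAAA")),
               c(1L, NA_integer_))
})

test_that("paired duplicate decisions require both mates to match", {
  spec <- comparatorSpec("tight")
  a <- makeUnits("ACGT", "GGGG")
  b <- makeUnits("ACGT", "GGGT")
  expect_false(unitIsDuplicate(b, a, spec))
  b2 <- makeUnits("ACGT", "GGGG")
  expect_true(unitIsDuplicate(b2, a, spec))
  # loose applies the prefix rule per mate
  a3 <- makeUnits("ACGT", "GG")
  b3 <- makeUnits("ACGTAA", "GGGG")
  expect_true(unitIsDuplicate(b3, a3, comparatorSpec("loose")))
  expect_error(unitIsDuplicate(makeUnits("ACGT"), a, spec),
               class = "fqdedup_contract_violation")
})

test_that("scan semantics: representative groups and predecessor chains", {
  scanIds <- function(seqs, spec) {
    u <- makeUnits(seqs)  # already sorted in these fixtures
    collectUnits(scanDedup(unitStreamer(u, 2L), spec)$stream)$seq1
  }
  expect_equal(scanIds(c("AAAA", "AAAA", "AAAT"), comparatorSpec("tight")),
               c("AAAA", "AAAT"))
  # tail-hamming compares to the immediate predecessor, kept or not, so
  # removal chains through reads that differ pairwise by <= k but whose
  # endpoints differ by more (the transitivity ambiguity)
  expect_equal(scanIds(c("AAAA", "AAAT", "AATT"),
                       comparatorSpec("tail_hamming", hammingMax = 1)),
               "AAAA")
  # ...whereas tight keeps the distinct sequences
  expect_equal(scanIds(c("AAAA", "AAAT", "AATT"), comparatorSpec("tight")),
               c("AAAA", "AAAT", "AATT"))
  # loose: extensions of the representative's prefix collapse into it
  expect_equal(scanIds(c("AC", "ACA", "ACG"), comparatorSpec("loose")), "AC")
  # unsorted input is a contract violation
  u <- makeUnits(c("TTTT", "AAAA"))
  expect_error(collectUnits(scanDedup(unitStreamer(u), comparatorSpec())$stream),
               class = "fqdedup_contract_violation")
})

test_that("streaming pipeline matches the naive oracle in every mode", {
  tmp <- withr::local_tempdir()
  for (paired in c(FALSE, TRUE)) {
    u <- randomDupUnits(1500, len = 24, paired = paired, seed = 17 + paired)
    for (spec in allSpecs()) {
      kept <- pipelineDedup(u, spec, budget = 40000, tmpdir = tmp)
      expect_setequal(kept$id1, oracleSeqBased(u, spec))
    }
  }
})

test_that("mode identities hold: k=0 is tight; loose is tight at equal length", {
  u <- randomDupUnits(800, len = 20, seed = 23)          # mixed lengths
  eq <- makeUnits(randomSeqVec(400, 15)[sample.int(400, 800, TRUE)])
  tmp <- withr::local_tempdir()
  tight <- pipelineDedup(u, comparatorSpec("tight"), tmpdir = tmp)
  th0 <- pipelineDedup(u, comparatorSpec("tail_hamming", hammingMax = 0),
                       tmpdir = tmp)
  expect_setequal(th0$id1, tight$id1)
  looseEq <- pipelineDedup(eq, comparatorSpec("loose"), tmpdir = tmp)
  tightEq <- pipelineDedup(eq, comparatorSpec("tight"), tmpdir = tmp)
  expect_setequal(looseEq$id1, tightEq$id1)
  # tight leaves no two identical sequences, keeping the lowest input index
  expect_false(any(duplicated(tight$seq1)))
  firstIdx <- tapply(u$index, u$seq1, min)
  expect_setequal(tight$index, unname(firstIdx[unique(u$seq1)]))
})

test_that("tight and loose are idempotent; a tail-hamming repass never grows", {
  tmp <- withr::local_tempdir()
  u <- randomDupUnits(1200, len = 18, seed = 29)
  for (mode in c("tight", "loose")) {
    spec <- comparatorSpec(mode)
    once <- pipelineDedup(u, spec, tmpdir = tmp)
    twice <- pipelineDedup(once, spec, tmpdir = tmp)
    expect_identical(sort(twice$id1), sort(once$id1))
  }
  th <- comparatorSpec("tail_hamming", hammingMax = 2)
  once <- pipelineDedup(u, th, tmpdir = tmp)
  twice <- pipelineDedup(once, th, tmpdir = tmp)
  expect_lte(nrow(twice), nrow(once))
})

test_that("file-level sequence-based runs keep records verbatim and in sync", {
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "in_1.fq")
  f2 <- file.path(tmp, "in_2.fq")
  synthesizeLibrary(f1, f2, templates = 40, readsPerTemplate = 4,
                    errorRate = 0.15, truncationFraction = 0.1, seed = 5)
  o1 <- file.path(tmp, "out_1.fq")
  o2 <- file.path(tmp, "out_2.fq")
  stats <- runSeqBased(f1, o1, f2, o2, spec = comparatorSpec("loose"),
                       budget = memoryBudget(16), tmpdir = tmp)
  input <- readUnits(f1, f2)
  kept <- readUnits(o1, o2)
  expect_equal(nrow(kept), keptReads(stats))
  expect_setequal(kept$id1, oracleSeqBased(input, comparatorSpec("loose")))
  # pair atomicity: mates aligned row by row, fields byte-identical to input
  expect_identical(kept$id1, kept$id2)
  src <- input[match(kept$id1, input$id1), c("seq1", "qual1", "seq2", "qual2")]
  rownames(src) <- NULL
  expect_identical(kept[, c("seq1", "qual1", "seq2", "qual2")], src)
  # no stray temp files
  expect_length(list.files(tmp, pattern = "\\.run$"), 0L)
})

test_that("loose-mode paired results depend on input file order", {
  # three pairs where the hub pair (both-mates prefixes) differs by
  # orientation: forward collapses all three, swapped keeps two
  u1 <- c("AC", "AT", "A")
  u2 <- c("GC", "G", "GCA")
  tmp <- withr::local_tempdir()
  fwd <- pipelineDedup(makeUnits(u1, u2), comparatorSpec("loose"), tmpdir = tmp)
  rev <- pipelineDedup(makeUnits(u2, u1), comparatorSpec("loose"), tmpdir = tmp)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 2L)
})

test_that("FASTA input deduplicates and round trips without qualities", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "in.fa")
  synthesizeLibrary(f, templates = 25, readsPerTemplate = 4, seed = 31,
                    format = "fasta")
  o <- file.path(tmp, "out.fa")
  st <- runSeqBased(f, o, budget = memoryBudget(16), tmpdir = tmp)
  expect_equal(keptReads(st), 25)
  kept <- parseRecords(o)
  expect_true(all(is.na(kept$quality)))
  input <- parseRecords(f)
  expect_setequal(kept$sequence, unique(input$sequence))
})

test_that("dedup applied twice to files is a fixed point", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "in.fq")
  synthesizeLibrary(f, templates = 30, readsPerTemplate = 5, seed = 9)
  o1 <- file.path(tmp, "o1.fq")
  o2 <- file.path(tmp, "o2.fq")
  s1 <- runSeqBased(f, o1, budget = memoryBudget(16), tmpdir = tmp)
  s2 <- runSeqBased(o1, o2, budget = memoryBudget(16), tmpdir = tmp)
  expect_equal(removedReads(s2), 0)
  expect_identical(readLines(o2), readLines(o1))
})
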