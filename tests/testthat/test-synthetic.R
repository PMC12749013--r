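test_that("template generation is seeded, validated, and collision-free", {
  a <- generateTemplates(3, c(50, 50), seed = 7)
  b <- generateTemplates(3, c(50, 50), seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generateTemplates(3, c(50, 50), seed = 8)))
  expect_equal(nrow(generateTemplates(0)), 0L)
  expect_error(generateTemplates(5, c(10, 2)), class = "fqdedup_usage_error")
  expect_error(generateTemplates(-1), class = "fqdedup_usage_error")
  # birthday bound: 1000 random 30-mers have ~C(1000,2)/4^30 collision mass
  tpl <- generateTemplates(1000, c(30, 30), seed = 1)
  expect_false(any(duplicated(tpl$seq1)))
  pe <- generateTemplates(10, c(20, 25), paired = TRUE, seed = 2)
  expect_true(all(nchar(pe$seq2) %in% 20:25))
})

test_that("error-free amplification yields exactly the planted duplicates", {
  tpl <- generateTemplates(10, c(60, 60), seed = 3)
  amp <- amplifyTemplates(tpl, copies = 4, seed = 4)
  expect_equal(nrow(amp$reads), 50L)
  expect_equal(nrow(amp$manifest), 50L)
  expect_equal(sum(amp$manifest$class == "original"), 10L)
  expect_equal(sum(amp$manifest$class == "exact_pcr_copy"), 40L)
  # tight dedup recovers the template count
  u <- amp$reads
  u$index <- seq_len(nrow(u)) - 1L
  expect_length(oracleSeqBased(u, comparatorSpec("tight")), 10L)
  expect_error(amplifyTemplates(tpl, copies = 0), class = "fqdedup_usage_error")
})

test_that("fully truncated libraries collapse under loose but not tight", {
  tpl <- generateTemplates(12, c(80, 80), seed = 5)
  amp <- amplifyTemplates(tpl, copies = 3, truncationFraction = 1,
                          truncationRange = c(5, 20), seed = 6)
  u <- amp$reads
  u$index <- seq_len(nrow(u)) - 1L
  expect_length(oracleSeqBased(u, comparatorSpec("loose")), 12L)
  # tight keeps originals plus every distinct truncated length per template
  expect_length(oracleSeqBased(u, comparatorSpec("tight")),
                length(unique(toupper(u$seq1))))
  expect_true(all(amp$manifest$class[13:48] == "truncated_copy"))
  expect_error(
    amplifyTemplates(generateTemplates(2, c(10, 10), seed = 1), copies = 2,
                     truncationFraction = 1, truncationRange = c(10, 12),
                     seed = 1),
    "truncation longer", class = "fqdedup_usage_error")
})

test_that("tail-error copies carry substitutions only near the 3' end", {
  tpl <- generateTemplates(30, c(100, 100), seed = 8)
  amp <- amplifyTemplates(tpl, copies = 3,
                          errorModel = tailErrorModel(0.15, tailStart = 0.8),
                          seed = 9)
  errRows <- which(amp$manifest$class == "tail_error_copy")
  expect_gt(length(errRows), 0L)
  tplSeq <- tpl$seq1[match(amp$manifest$template_id[errRows], tpl$template_id)]
  readSeq <- amp$reads$seq1[errRows]
  d <- hammingDistance(readSeq, tplSeq)
  expect_true(all(d >= 1L))
  # every mismatch lies in the final 20% of positions
  for (i in seq_along(errRows)) {
    mism <- which(utf8ToInt(readSeq[i]) != utf8ToInt(tplSeq[i]))
    expect_true(all(mism > 80))
  }
  # a copy with exactly one tail mismatch is removable by tail-hamming k=1
  # when adjacent, never by tight
  one <- which(d == 1L)[1]
  expect_false(is.na(one))
  expect_true(compareTailHamming(readSeq[one], tplSeq[one], 1))
  expect_false(compareTight(readSeq[one], tplSeq[one]))
})

test_that("emitted datasets are deterministic and round trip with the manifest", {
  tmp <- withr::local_tempdir()
  f1a <- file.path(tmp, "a_1.fq")
  f2a <- file.path(tmp, "a_2.fq")
  f1b <- file.path(tmp, "b_1.fq")
  f2b <- file.path(tmp, "b_2.fq")
  synthesizeLibrary(f1a, f2a, templates = 20, readsPerTemplate = 3,
                    errorRate = 0.1, truncationFraction = 0.2, seed = 42)
  synthesizeLibrary(f1b, f2b, templates = 20, readsPerTemplate = 3,
                    errorRate = 0.1, truncationFraction = 0.2, seed = 42)
  expect_identical(readLines(f1a), readLines(f1b))
  expect_identical(readLines(f2a), readLines(f2b))
  # manifest covers every emitted read exactly once
  man <- read.delim(paste0(f1a, ".manifest.tsv"))
  u <- readUnits(f1a, f2a)
  expect_setequal(man$read_id, u$id1)
  expect_false(any(duplicated(man$read_id)))
  expect_true(all(man$class %in% c("original", "exact_pcr_copy",
                                   "tail_error_copy", "truncated_copy")))
  # gz emission parses back to identical records
  fgz <- file.path(tmp, "c.fq.gz")
  synthesizeLibrary(fgz, templates = 20, readsPerTemplate = 3, seed = 42,
                    compression = "gzip")
  fpl <- file.path(tmp, "c.fq")
  synthesizeLibrary(fpl, templates = 20, readsPerTemplate = 3, seed = 42)
  expect_identical(readUnits(fgz), readUnits(fpl))
})
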