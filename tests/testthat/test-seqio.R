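test_that("FASTQ parsing handles well-formed, commented and CRLF records", {
  f <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2 lane=3 extra", "acgTN", "+r2", "ABCDE"), f)
  rec <- parseRecords(f)
  expect_equal(rec$id, c("r1", "r2"))
  expect_equal(rec$comment, c("", "lane=3 extra"))
  expect_equal(rec$sequence, c("ACGT", "acgTN"))  # case preserved verbatim
  expect_equal(rec$quality, c("IIII", "ABCDE"))

  crlf <- tempfile(fileext = ".fq")
  writeBin(charToRaw("@r1\r\nACGT\r\n+\r\nIIII\r\n"), crlf)
  expect_equal(parseRecords(crlf)$sequence, "ACGT")
})

test_that("malformed FASTQ is rejected with the record ordinal", {
  f <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+"), f)  # truncated block
  expect_error(parseRecords(f), "record 1", class = "fqdedup_malformed_input")

  g <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), g)
  expect_error(parseRecords(g), "record 2", class = "fqdedup_malformed_input")

  h <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "x", "IIII"), h)
  expect_error(parseRecords(h), class = "fqdedup_malformed_input")
})

test_that("FASTA sequences spanning multiple lines are concatenated", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">r1", "AC", "GT", ">r2 desc here", "TTTT", ">r3", ""), f)
  rec <- parseRecords(f)
  expect_equal(rec$sequence, c("ACGT", "TTTT", ""))
  expect_equal(rec$comment, c("", "desc here", ""))
  expect_true(all(is.na(rec$quality)))
})

test_that("FASTA streaming yields identical records to whole-file parsing", {
  set.seed(41)
  n <- 500
  f <- tempfile(fileext = ".fa")
  seqs <- randomSeqVec(n, 120)
  # wrap sequences at 50 columns so records span lines and chunk boundaries
  lines <- unlist(lapply(seq_len(n), function(i) {
    c(paste0(">s", i),
      substring(seqs[i], seq(1, 120, 50), pmin(seq(1, 120, 50) + 49, 120)))
  }))
  writeLines(lines, f)
  s <- recordStreamer(f, chunkSize = 37L)
  rec <- collectUnits(s)
  expect_equal(rec$id, paste0("s", seq_len(n)))
  expect_equal(rec$sequence, seqs)
})

test_that("write/parse round trip preserves all fields, plain and gzip", {
  set.seed(7)
  n <- 1000
  rec <- data.frame(
    id = sprintf("read:%04d/1", seq_len(n)),
    comment = ifelse(seq_len(n) %% 3 == 0, sprintf("c %d x=%d", seq_len(n), n), ""),
    sequence = randomSeqVec(n, 30),
    quality = vapply(seq_len(n),
                     function(i) intToUtf8(sample(33:73, 30, TRUE)), ""))
  for (ext in c(".fq", ".fq.gz")) {
    f <- tempfile(fileext = ext)
    expect_equal(writeRecords(rec, f), n)
    expect_equal(detectCompression(f), if (ext == ".fq") "none" else "gzip")
    back <- parseRecords(f)
    expect_identical(back, rec)
  }
  # FASTA round trip drops qualities only
  fa <- tempfile(fileext = ".fa")
  recf <- rec
  recf$quality <- NA_character_
  writeRecords(recf, fa)
  expect_identical(parseRecords(fa), recf)
})

test_that("empty inputs and outputs are handled as degenerate, not errors", {
  f <- tempfile()
  file.create(f)
  expect_equal(detectCompression(f), "none")
  expect_equal(nrow(parseRecords(f, format = "fastq")), 0L)
  out <- tempfile(fileext = ".fq")
  expect_equal(writeRecords(parseRecords(f, format = "fastq"), out), 0L)
  expect_equal(nrow(parseRecords(out, format = "fastq")), 0L)
})

test_that("compression detection uses magic bytes, not the file name", {
  gz <- tempfile(fileext = ".dat")
  con <- gzfile(gz, "wt")
  writeLines(c("@r1", "ACGT", "+", "IIII"), con)
  close(con)
  expect_equal(detectCompression(gz), "gzip")
  expect_equal(parseRecords(gz, format = "fastq")$sequence, "ACGT")
  expect_error(detectCompression(tempfile()), class = "fqdedup_io_error")
})

test_that("paired reading is positional, symmetric, and aborts on desync", {
  f1 <- tempfile(fileext = ".fq")
  f2 <- tempfile(fileext = ".fq")
  writeLines(c("@a1", "AAAA", "+", "IIII", "@a2", "CCCC", "+", "IIII"), f1)
  writeLines(c("@b1", "GGGG", "+", "IIII", "@b2", "TTTT", "+", "IIII"), f2)
  u <- collectUnits(pairedReader(f1, f2))
  expect_equal(u$index, 0:1)
  expect_equal(u$id1, c("a1", "a2"))
  expect_equal(u$id2, c("b1", "b2"))
  swapped <- collectUnits(pairedReader(f2, f1))
  expect_equal(swapped$id1, u$id2)
  expect_equal(swapped$id2, u$id1)

  f3 <- tempfile(fileext = ".fq")
  writeLines(c("@b1", "GGGG", "+", "IIII", "@b2", "TTTT", "+", "IIII",
               "@b3", "ACGT", "+", "IIII"), f3)
  expect_error(collectUnits(pairedReader(f1, f3)), "2 vs 3",
               class = "fqdedup_sync_error")
})

test_that("paired writing keeps mates synchronized and round trips", {
  u <- makeUnits(c("ACGT", "TTAA"), c("GGCC", "CCGG"))
  f1 <- tempfile(fileext = ".fq")
  f2 <- tempfile(fileext = ".fq.gz")
  counts <- pairedWriter(u, f1, f2)
  expect_equal(unname(counts), c(2L, 2L))
  back <- readUnits(f1, f2)
  expect_identical(back, u)
  # zero units still produce two (empty) files
  e1 <- tempfile(fileext = ".fq")
  e2 <- tempfile(fileext = ".fq")
  pairedWriter(u[0, , drop = FALSE], e1, e2)
  expect_true(file.exists(e1) && file.exists(e2))
  # single-end units through the paired writer violate the contract
  expect_error(pairedWriter(makeUnits("ACGT"), f1, f2),
               class = "fqdedup_contract_violation")
})
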