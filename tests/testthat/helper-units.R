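# Shared fixture builders.  All data are generated in code at test time.

# Unit frame from bare sequences (single- or paired-end).
makeUnits <- function(seqs1, seqs2 = NULL, ids = NULL, quals = TRUE) {
  n <- length(seqs1)
  if (is.null(ids)) ids <- sprintf("r%04d", seq_len(n))
  u <- data.frame(
    index = seq_len(n) - 1L,
    id1 = ids, comment1 = "",
    seq1 = seqs1,
    qual1 = if (quals) strrep("I", nchar(seqs1)) else NA_character_)
  if (!is.null(seqs2)) {
    u$id2 <- ids
    u$comment2 <- ""
    u$seq2 <- seqs2
    u$qual2 <- if (quals) strrep("I", nchar(seqs2)) else NA_character_
  }
  u
}

randomSeqVec <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, asplit(m, 2))
}

# A shuffled library with planted exact duplicates, near-duplicates (tail
# substitutions) and truncations, plus enough distinct reads to exercise all
# modes.  Returns a unit frame.
randomDupUnits <- function(n, len = 40, paired = FALSE, seed = 1) {
  set.seed(seed)
  nTpl <- max(1L, n %/% 4L)
  tpl1 <- randomSeqVec(nTpl, len)
  tpl2 <- if (paired) randomSeqVec(nTpl, len)
  pick <- sample.int(nTpl, n, replace = TRUE)
  mutate1 <- function(s) {
    # substitute the final base of some reads, truncate others
    r <- runif(length(s))
    sub <- r < 0.25
    substr(s[sub], nchar(s[sub]), nchar(s[sub])) <-
      sample(c("A", "C", "G", "T"), sum(sub), replace = TRUE)
    trunc <- r > 0.85
    s[trunc] <- substr(s[trunc], 1L, nchar(s[trunc]) - sample(1:5, sum(trunc), replace = TRUE))
    s
  }
  s1 <- mutate1(tpl1[pick])
  s2 <- if (paired) mutate1(tpl2[pick])
  makeUnits(s1, s2)
}

writeFastqFile <- function(units, path, path2 = NULL, compression = "none") {
  writeUnits(units, path, path2, format = "fastq", compression = compression)
  invisible(path)
}

allSpecs <- function() list(
  tight = comparatorSpec("tight"),
  loose = comparatorSpec("loose"),
  th0 = comparatorSpec("tail_hamming", hammingMax = 0),
  th1 = comparatorSpec("tail_hamming", hammingMax = 1),
  th2 = comparatorSpec("tail_hamming", hammingMax = 2)
)

# Full streaming pipeline on an in-memory unit frame: external sort +
# single-pass scan; returns the kept unit frame.
pipelineDedup <- function(units, spec, budget = memoryBudget(16),
                          tmpdir = tempdir(), chunkSize = 997L) {
  sorted <- externalSort(unitStreamer(units, chunkSize), sortKey, budget,
                         tmpdir = tmpdir)
  collectUnits(scanDedup(sorted, spec)$stream)
}
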