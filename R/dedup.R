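# The sequence-based deduplication engine: sort keys, the three duplicate
# definitions, paired-end coupling, and the single pass over the sorted
# stream.

MODE_CODE <- c(tight = 1L, loose = 2L, tail_hamming = 3L)

#' Sequence sort key of deduplication units
#'
#' Single-end units key on the uppercased sequence bytes.  Paired-end units
#' concatenate left and right sequences around a 0x01 sentinel byte, which
#' sorts before every base letter so that a left-mate prefix sorts before
#' all of its extensions.  Keys are compared byte-wise (C locale); all
#' sorting in the package uses `order(..., method = "radix")`.
#'
#' @param units A unit frame.
#' @return Character vector of byte-comparable sort keys.
#' @export
sortKey <- function(units) {
  k <- toupper(units$seq1)
  if (isPairedUnits(units))
    k <- paste0(k, "\x01", toupper(units$seq2))
  k
}

#' Pairwise duplicate definitions
#'
#' Vectorized comparators over pairs of sequences (case-insensitive):
#'
#' * `compareTight()`: exact equality; different lengths are never
#'   duplicates.
#' * `compareLoose()`: the shorter sequence equals the prefix of the longer
#'   (equal lengths reduce to equality).
#' * `compareTailHamming()`: equal length and Hamming distance at most `k`;
#'   different lengths are never duplicates (Hamming distance is undefined
#'   otherwise, mirroring the tight-mode length rule).
#'
#' @param a,b Character vectors of sequences (recycled to common length).
#' @param k Non-negative mismatch budget.
#' @return Logical vector.
#' @examples
#' compareTight("ACGT", "ACGTA")        # FALSE
#' compareLoose("ACGT", "ACGTAA")       # TRUE
#' compareTailHamming("ACGT", "ACGA", 1) # TRUE
#' @export
compareTight <- function(a, b) {
  toupper(a) == toupper(b)
}

#' @rdname compareTight
#' @export
compareLoose <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  m <- pmin(nchar(a), nchar(b))
  substr(a, 1L, m) == substr(b, 1L, m)
}

#' @rdname compareTight
#' @export
compareTailHamming <- function(a, b, k) {
  if (k < 0) fqStop("usage_error", "hamming threshold must be >= 0")
  d <- hammingDistance(a, b)
  !is.na(d) & d <= k
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character vectors, recycled to common length.
#' @return Integer vector of positional mismatch counts; `NA` where lengths
#'   differ.
#' @export
hammingDistance <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  n <- max(length(a), length(b))
  hamming_cpp(rep_len(a, n), rep_len(b, n))
}

#' Test whether one unit is a duplicate of a reference unit
#'
#' Single-end units apply the selected comparator to the sequences.  For
#' paired-end units the comparison must hold for left-vs-left **and**
#' right-vs-right; a pair is removed only as a whole.
#'
#' @param candidate,reference Single-row unit frames of equal pairedness.
#' @param spec A [comparatorSpec()].
#' @return `TRUE` or `FALSE`.
#' @export
unitIsDuplicate <- function(candidate, reference, spec = comparatorSpec()) {
  if (isPairedUnits(candidate) != isPairedUnits(reference))
    fqStop("contract_violation",
           "candidate and reference differ in pairedness")
  cmp <- switch(spec@mode,
    tight = compareTight,
    loose = compareLoose,
    tail_hamming = function(a, b) compareTailHamming(a, b, spec@hammingMax))
  ok <- cmp(candidate$seq1, reference$seq1)
  if (isPairedUnits(candidate))
    ok <- ok & cmp(candidate$seq2, reference$seq2)
  as.logical(ok)
}

newScanState <- function() {
  list(has = FALSE, refL = "", refR = "", predL = "", predR = "")
}

#' Remove duplicates in a single pass over a sorted unit stream
#'
#' The first unit is always kept.  In tight and loose modes each unit is
#' compared against the current group representative (the first kept unit of
#' the group); when the comparison fails the unit is kept and becomes the
#' new representative.  In tail-hamming mode each unit is compared against
#' its immediate predecessor in the sorted stream, kept or not, so removal
#' can chain through intermediate reads (the transitivity ambiguity inherent
#' to mismatch-tolerant duplicate definitions).  Input must be sorted by
#' `(sortKey, index)`; a key decrease raises a contract violation.
#'
#' @param stream A streamer of sorted unit frames (see [externalSort()]).
#' @param spec A [comparatorSpec()].
#' @return A list with `stream` (streamer of kept units) and `stats` (an
#'   environment with `total` and `kept`, valid once the stream is
#'   exhausted).
#' @export
scanDedup <- function(stream, spec = comparatorSpec()) {
  mode <- MODE_CODE[[spec@mode]]
  k <- spec@hammingMax
  state <- newScanState()
  lastKey <- NULL
  stats <- new.env(parent = emptyenv())
  stats$total <- 0
  stats$kept <- 0
  out <- function() {
    repeat {
      batch <- stream()
      if (is.null(batch)) return(NULL)
      if (!nrow(batch)) next
      keys <- sortKey(batch)
      prev <- c(lastKey %||% keys[1L], keys[-length(keys)])
      if (any(str_lt_cpp(keys, prev)))
        fqStop("contract_violation",
               "scanDedup input is not sorted by (sortKey, index)")
      lastKey <<- keys[length(keys)]
      paired <- isPairedUnits(batch)
      res <- scan_chunk_cpp(
        toupper(batch$seq1),
        if (paired) toupper(batch$seq2) else NULL,
        mode, k, state)
      state <<- res$state
      stats$total <- stats$total + nrow(batch)
      stats$kept <- stats$kept + sum(res$keep)
      kept <- batch[res$keep, , drop = FALSE]
      rownames(kept) <- NULL
      return(kept)
    }
  }
  list(stream = out, stats = stats)
}

#' Sequence-based deduplication of read files
#'
#' The full streaming pipeline: read single-end or paired-end FASTQ/FASTA
#' (plain or gzip), externally sort units by sequence under the memory
#' budget, remove duplicates in a single pass under the selected duplicate
#' definition, and write the kept units (in sorted order) with ids,
#' sequences and qualities unchanged.  Paired outputs stay synchronized:
#' a pair is kept or removed as a whole.  Among duplicates, the unit with
#' the lowest original input position is the one retained.  All temporary
#' files live in a private subdirectory of `tmpdir` and are removed on every
#' exit path.
#'
#' @param input1,input2 Input paths (`input2 = NULL` for single-end).
#' @param output1,output2 Output paths, matching the inputs.
#' @param spec A [comparatorSpec()].
#' @param budget A [memoryBudget()] or byte count.
#' @param tmpdir Directory for temporary run files.
#' @param format,compression Input handling, as in [recordStreamer()].
#' @param outCompression `"auto"` (gzip iff the output path ends in `.gz`),
#'   `"none"` or `"gzip"`.
#' @return A [`DedupStats`][DedupStats-class] object.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@a", "ACGT", "+", "IIII", "@b", "ACGT", "+", "IIII"), fq)
#' out <- tempfile(fileext = ".fq")
#' runSeqBased(fq, out)
#' @export
runSeqBased <- function(input1, output1, input2 = NULL, output2 = NULL,
                        spec = comparatorSpec(), budget = memoryBudget(),
                        tmpdir = tempdir(), format = "auto",
                        compression = "auto", outCompression = "auto") {
  paired <- !is.null(input2)
  if (paired && is.null(output2))
    fqStop("usage_error", "paired-end input requires two output paths")
  if (!paired && !is.null(output2))
    fqStop("usage_error", "single-end input takes a single output path")
  sessionTmp <- tempfile("fqdedup", tmpdir = tmpdir)
  dir.create(sessionTmp)
  ok <- FALSE
  on.exit({
    unlink(sessionTmp, recursive = TRUE, force = TRUE)
    if (!ok) {
      unlink(output1)
      if (!is.null(output2)) unlink(output2)
    }
  })
  fmt <- resolveFormat(input1, format, compression)
  stream <- unitReader(input1, input2, format = fmt, compression = compression)
  sorted <- externalSort(stream, sortKey, budget, tmpdir = sessionTmp)
  acct <- attr(sorted, "acct")
  scanned <- scanDedup(sorted, spec)
  writeUnits(scanned$stream, output1, output2, format = fmt,
             compression = outCompression)
  ok <- TRUE
  dedupStats(total = scanned$stats$total, kept = scanned$stats$kept,
             mode = spec@mode, paired = paired,
             tempBytes = acct$tempBytes, inputBytes = acct$inputBytes)
}
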