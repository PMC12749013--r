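# Fast mode: in-memory exact deduplication keyed on sequences packed into
# 64-bit words, preserving input order.  No memory cap applies in this mode;
# the key set grows with the number of distinct sequences.

#' Pack a nucleotide sequence into 64-bit words
#'
#' Encodes a sequence at 4 bits per base into 64-bit words, 16 bases per
#' word, base i occupying the (i mod 16)-th nibble from the most-significant
#' end of word i %/% 16, with unused trailing nibbles zero.  The 16-symbol
#' code table covers `A C G T N R Y S W K M B D H V U` (in that order,
#' codes 0-15), so ambiguous and IUPAC bases stay distinct: the encoding is
#' injective given the explicit base count.  Lowercase input is uppercased
#' first; any other symbol raises an error naming its position.
#'
#' @param seq A single sequence string.
#' @param x A `PackedSeq`.
#' @return A [`PackedSeq`][PackedSeq-class] object.
#' @examples
#' packSequence("ACGT")   # one word, 0x0123000000000000
#' @export
packSequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  p <- tryCatch(pack_sequence_cpp(toupper(seq)),
                error = function(e) fqStop("unsupported_symbol", "%s",
                                           conditionMessage(e)))
  new("PackedSeq", words = as.character(p$words), length = p$length)
}

fastKeys <- function(units) {
  packOrStop <- function(x) {
    tryCatch(pack_keys_cpp(toupper(x)),
             error = function(e) fqStop("unsupported_symbol", "%s",
                                        conditionMessage(e)))
  }
  k <- packOrStop(units$seq1)
  if (isPairedUnits(units))
    k <- paste(k, packOrStop(units$seq2), sep = "|")
  k
}

#' Exact deduplication via packed-sequence keys
#'
#' Keys each unit on the packed form of its sequence (pair of packed forms
#' for paired-end units), keeps the first occurrence of every distinct key
#' and drops the rest.  Output preserves input order.  Keys are full packed
#' encodings, not hashes, so no false-positive removal is possible; the kept
#' set is identical to tight mode's.
#'
#' @param units A unit frame or unit streamer.
#' @return A list with `kept` (unit frame in input order) and `stats`
#'   (a [`DedupStats`][DedupStats-class]).
#' @examples
#' u <- data.frame(index = 0:2, id1 = c("r1", "r2", "r3"), comment1 = "",
#'                 seq1 = c("ACGT", "ACGT", "ACGA"), qual1 = "IIII")
#' fastDedup(u)$kept$id1
#' @export
fastDedup <- function(units) {
  stream <- if (is.function(units)) units else unitStreamer(units)
  seen <- character(0)
  keptParts <- list()
  total <- 0
  paired <- FALSE
  repeat {
    b <- stream()
    if (is.null(b)) break
    if (!nrow(b)) next
    paired <- isPairedUnits(b)
    keys <- fastKeys(b)
    keep <- !duplicated(keys) & !(keys %in% seen)
    seen <- c(seen, keys[keep])
    total <- total + nrow(b)
    keptParts[[length(keptParts) + 1L]] <- b[keep, , drop = FALSE]
  }
  kept <- if (length(keptParts)) {
    k <- data.table::rbindlist(keptParts)
    data.table::setDF(k)
    rownames(k) <- NULL
    k
  } else data.frame()
  list(kept = kept,
       stats = dedupStats(total = total, kept = nrow(kept), mode = "fast",
                          paired = paired))
}

#' Fast-mode deduplication of read files
#'
#' File-level wrapper around [fastDedup()]: streams the input(s), keeps the
#' first occurrence of every distinct sequence (pair), and writes kept reads
#' in their original input order.  Uses no temporary files; memory grows
#' with the number of distinct sequences and cannot be limited in this mode.
#'
#' @inheritParams runSeqBased
#' @return A [`DedupStats`][DedupStats-class] object.
#' @export
runFast <- function(input1, output1, input2 = NULL, output2 = NULL,
                    format = "auto", compression = "auto",
                    outCompression = "auto") {
  paired <- !is.null(input2)
  if (paired && is.null(output2))
    fqStop("usage_error", "paired-end input requires two output paths")
  if (!paired && !is.null(output2))
    fqStop("usage_error", "single-end input takes a single output path")
  fmt <- resolveFormat(input1, format, compression)
  stream <- unitReader(input1, input2, format = fmt, compression = compression)
  seen <- character(0)
  total <- 0
  kept <- 0
  wL <- recordWriter(output1, fmt, outCompression)
  wR <- if (paired) recordWriter(output2, fmt, outCompression)
  ok <- FALSE
  on.exit(if (!ok) {
    try(wL$close(), silent = TRUE)
    if (!is.null(wR)) try(wR$close(), silent = TRUE)
    unlink(output1)
    if (!is.null(output2)) unlink(output2)
  })
  repeat {
    b <- stream()
    if (is.null(b)) break
    if (!nrow(b)) next
    keys <- fastKeys(b)
    keep <- !duplicated(keys) & !(keys %in% seen)
    seen <- c(seen, keys[keep])
    total <- total + nrow(b)
    kept <- kept + sum(keep)
    kb <- b[keep, , drop = FALSE]
    wL$write(unitsToRecords(kb, 1L))
    if (paired) wR$write(unitsToRecords(kb, 2L))
  }
  ok <- TRUE
  wL$close()
  if (paired) wR$close()
  dedupStats(total = total, kept = kept, mode = "fast", paired = paired)
}
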