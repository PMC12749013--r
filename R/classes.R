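# S4 value classes: comparator configuration, memory budget, packed
# sequences, and run statistics.

#' Duplicate-definition selector
#'
#' `ComparatorSpec` selects one of the three sequence-based duplicate
#' definitions and, for the tail-hamming definition, the mismatch budget.
#'
#' * `tight` (the default): two reads are duplicates only when their
#'   sequences are identical over the full length; different lengths are
#'   never duplicates.
#' * `loose`: the shorter sequence must equal the prefix of the longer
#'   (FastUniq-style); equal lengths reduce to plain equality.
#' * `tail_hamming`: reads adjacent in the sequence-sorted stream are
#'   duplicates when they have equal length and Hamming distance at most
#'   `hammingMax`; motivated by substitution errors concentrating near read
#'   3' ends.
#'
#' For paired-end units a candidate pair is a duplicate only when the chosen
#' comparison holds for the left mates **and** for the right mates.
#'
#' @param mode One of `"tight"`, `"loose"`, `"tail_hamming"`
#'   (`"tail-hamming"` is accepted as an alias).
#' @param hammingMax Non-negative mismatch budget; only consulted in
#'   tail-hamming mode.
#' @return A `ComparatorSpec` object.
#' @examples
#' comparatorSpec()
#' comparatorSpec("tail-hamming", hammingMax = 2)
#' @name ComparatorSpec-class
#' @aliases ComparatorSpec
#' @export comparatorSpec
#' @exportClass ComparatorSpec
setClass("ComparatorSpec",
  representation(mode = "character", hammingMax = "integer"),
  validity = function(object) {
    if (length(object@mode) != 1L ||
        !object@mode %in% c("tight", "loose", "tail_hamming"))
      return("mode must be one of 'tight', 'loose', 'tail_hamming'")
    if (length(object@hammingMax) != 1L || is.na(object@hammingMax) ||
        object@hammingMax < 0L)
      return("hammingMax must be a single non-negative integer")
    TRUE
  }
)

comparatorSpec <- function(mode = c("tight", "loose", "tail_hamming", "tail-hamming"),
                           hammingMax = 0L) {
  mode <- match.arg(mode)
  if (mode == "tail-hamming") mode <- "tail_hamming"
  new("ComparatorSpec", mode = mode, hammingMax = as.integer(hammingMax))
}

#' @rdname ComparatorSpec-class
#' @param spec,object A `ComparatorSpec`.
#' @export
dedupMode <- function(spec) spec@mode

#' @rdname ComparatorSpec-class
#' @export
hammingMax <- function(spec) spec@hammingMax

#' @rdname ComparatorSpec-class
#' @export
setMethod("show", "ComparatorSpec", function(object) {
  cat("ComparatorSpec:", object@mode)
  if (object@mode == "tail_hamming")
    cat(" (hammingMax =", object@hammingMax, ")")
  cat("\n")
  invisible(object)
})

#' Memory budget for the sequence-based engine
#'
#' Caps the bytes of read data buffered in memory while building sorted runs
#' during the external sort.  The budget bounds buffering, not total process
#' RSS; a 16 MiB floor guarantees forward progress.  The default of
#' 2048 MiB reflects the engine's intended footprint of roughly 2 GB
#' independent of input size.
#'
#' @param mib Budget in mebibytes (>= 16).
#' @return A `MemoryBudget` object.
#' @examples
#' memoryBudget(16)
#' @name MemoryBudget-class
#' @aliases MemoryBudget
#' @export memoryBudget
#' @exportClass MemoryBudget
setClass("MemoryBudget",
  representation(bytes = "numeric"),
  validity = function(object) {
    if (length(object@bytes) != 1L || is.na(object@bytes))
      return("bytes must be a single number")
    if (object@bytes < 16 * 1024^2)
      return("memory budget must be at least 16 MiB")
    TRUE
  }
)

memoryBudget <- function(mib = 2048) {
  new("MemoryBudget", bytes = as.numeric(mib) * 1024^2)
}

#' @rdname MemoryBudget-class
#' @param budget A `MemoryBudget` or a numeric byte count.
#' @export
budgetBytes <- function(budget) {
  if (is(budget, "MemoryBudget")) return(budget@bytes)
  b <- as.numeric(budget)
  if (length(b) != 1L || is.na(b) || b <= 0)
    fqStop("usage_error", "invalid memory budget")
  b
}

#' @rdname MemoryBudget-class
#' @param object A `MemoryBudget`.
#' @export
setMethod("show", "MemoryBudget", function(object) {
  cat(sprintf("MemoryBudget: %.0f MiB\n", object@bytes / 1024^2))
  invisible(object)
})

#' Sequence packed into 64-bit words
#'
#' A nucleotide sequence encoded at 4 bits per base into 64-bit words
#' (16 bases per word), most-significant nibble first, with the base count
#' stored explicitly.  The 4-bit code covers the IUPAC alphabet plus U, so
#' ambiguous bases remain distinct symbols.  The encoding is injective:
#' two `PackedSeq` objects are identical iff the source sequences are equal.
#'
#' Words are stored as 16-digit lowercase hexadecimal strings (R has no
#' native unsigned 64-bit integer).
#'
#' @seealso [packSequence()]
#' @exportClass PackedSeq
setClass("PackedSeq",
  representation(words = "character", length = "integer"),
  validity = function(object) {
    if (length(object@length) != 1L || is.na(object@length) || object@length < 0L)
      return("length must be a single non-negative integer")
    if (length(object@words) != ceiling(object@length / 16))
      return("word count must equal ceiling(length/16)")
    TRUE
  }
)

#' @describeIn packSequence Hexadecimal 64-bit words of a `PackedSeq`.
#' @export
packedWords <- function(x) x@words

#' @describeIn packSequence Base count of a `PackedSeq`.
#' @export
packedLength <- function(x) x@length

#' @rdname packSequence
#' @param object A `PackedSeq`.
#' @export
setMethod("show", "PackedSeq", function(object) {
  cat(sprintf("PackedSeq: %d bases, %d word(s)\n", object@length,
              length(object@words)))
  if (length(object@words))
    cat(" ", paste0("0x", object@words), "\n")
  invisible(object)
})

#' Deduplication run statistics
#'
#' Totals reported by every deduplication entry point: units consumed, units
#' kept, units removed, plus the bytes of temporary run files written by the
#' external sort (`0` for the in-memory fast mode or when the input fits the
#' budget) and the byte size of the uncompressed input stream as consumed.
#'
#' @param stats,object A `DedupStats`.
#' @seealso [runSeqBased()], [runFast()], [reportStats()]
#' @exportClass DedupStats
setClass("DedupStats",
  representation(total = "numeric", kept = "numeric", removed = "numeric",
                 mode = "character", paired = "logical",
                 tempBytes = "numeric", inputBytes = "numeric"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@kept + object@removed, object@total)))
      return("kept + removed must equal total")
    if (object@total < 0) return("total must be non-negative")
    TRUE
  }
)

dedupStats <- function(total, kept, mode, paired, tempBytes = 0,
                       inputBytes = 0) {
  new("DedupStats", total = as.numeric(total), kept = as.numeric(kept),
      removed = as.numeric(total) - as.numeric(kept), mode = mode,
      paired = paired, tempBytes = as.numeric(tempBytes),
      inputBytes = as.numeric(inputBytes))
}

#' @describeIn DedupStats-class Units (reads or read pairs) consumed.
#' @export
totalReads <- function(stats) stats@total

#' @describeIn DedupStats-class Units kept.
#' @export
keptReads <- function(stats) stats@kept

#' @describeIn DedupStats-class Units removed as duplicates.
#' @export
removedReads <- function(stats) stats@removed

#' @describeIn DedupStats-class Percentage of units removed (0 for empty
#'   input).
#' @export
percentRemoved <- function(stats) {
  if (stats@total == 0) 0 else 100 * stats@removed / stats@total
}

#' @describeIn DedupStats-class Temporary run-file bytes written during the
#'   external sort.
#' @export
tempBytesWritten <- function(stats) stats@tempBytes

#' @rdname DedupStats-class
#' @export
setMethod("show", "DedupStats", function(object) {
  fmt <- function(x) format(x, big.mark = ",", scientific = FALSE)
  cat(sprintf(
    "DedupStats (%s%s): %s in, %s kept, %s removed (%.2f%%)\n",
    object@mode, if (object@paired) ", paired" else "",
    fmt(object@total), fmt(object@kept), fmt(object@removed),
    percentRemoved(object)))
  if (object@tempBytes > 0)
    cat(sprintf("  temp files written: %.1f MiB\n", object@tempBytes / 1024^2))
  invisible(object)
})
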