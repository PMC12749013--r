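# Naive reference implementations of every deduplication mode, used as
# independent ground truth in tests.  Deliberately simple, fully in-memory,
# plain-R loops sharing no code with the streaming engine beyond the
# definition of the (sequence key, index) sort order.  Quadratic-ish by
# intent; suitable for test-scale inputs only.

oracleMateDup <- function(a, b, mode, k) {
  if (mode == "tight") {
    a == b
  } else if (mode == "loose") {
    if (nchar(a) <= nchar(b)) substr(b, 1L, nchar(a)) == a
    else substr(a, 1L, nchar(b)) == b
  } else {
    nchar(a) == nchar(b) && sum(utf8ToInt(a) != utf8ToInt(b)) <= k
  }
}

#' Reference implementations of the deduplication modes
#'
#' `oracleSeqBased()` sorts the units in memory by `(sequence key, index)`
#' and replays the scan semantics literally: tight/loose compare against the
#' current group representative, tail-hamming against the immediate
#' predecessor in sorted order.  `oracleExact()` keeps the first occurrence
#' of each distinct sequence (pair) in input order using plain text keys, as
#' the reference for fast mode.  Both return the kept read identifiers as a
#' set (order unspecified).
#'
#' @param units An in-memory unit frame.
#' @param spec A [comparatorSpec()].
#' @return Character vector of kept `id1` values.
#' @export
oracleSeqBased <- function(units, spec = comparatorSpec()) {
  n <- nrow(units)
  if (!n) return(character(0))
  paired <- "seq2" %in% names(units)
  s1 <- toupper(units$seq1)
  s2 <- if (paired) toupper(units$seq2)
  key <- if (paired) paste(s1, s2, sep = "\x01") else s1
  o <- order(key, units$index, method = "radix")
  kept <- logical(n)
  mode <- spec@mode
  k <- spec@hammingMax
  refI <- o[1L]
  predI <- o[1L]
  kept[o[1L]] <- TRUE
  for (j in o[-1L]) {
    cmpI <- if (mode == "tail_hamming") predI else refI
    dup <- oracleMateDup(s1[j], s1[cmpI], mode, k) &&
      (!paired || oracleMateDup(s2[j], s2[cmpI], mode, k))
    if (!dup) {
      kept[j] <- TRUE
      if (mode != "tail_hamming") refI <- j
    }
    predI <- j
  }
  units$id1[kept]
}

#' @rdname oracleSeqBased
#' @export
oracleExact <- function(units) {
  if (!nrow(units)) return(character(0))
  key <- toupper(units$seq1)
  if ("seq2" %in% names(units))
    key <- paste(key, toupper(units$seq2), sep = "\x1e")
  units$id1[!duplicated(key)]
}
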