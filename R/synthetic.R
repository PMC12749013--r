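# Seeded generator of read libraries with known template/duplicate structure.
# Each emitted read is recorded in a truth manifest (read_id, template_id,
# class) so that every deduplication mode can be verified without external
# data: exact PCR copies are removable by every mode, tail-substituted
# copies only by tail-hamming (when within the mismatch budget and adjacent
# after sorting), 3'-truncated copies only by loose.

BASES <- c("A", "C", "G", "T")

randomSeqs <- function(lens) {
  n <- length(lens)
  if (!n) return(character(0))
  if (length(unique(lens)) == 1L) {
    L <- lens[1L]
    m <- matrix(sample(BASES, n * L, replace = TRUE), nrow = n)
    do.call(paste0, asplit(m, 2L))
  } else {
    ch <- sample(BASES, sum(lens), replace = TRUE)
    vapply(split(ch, rep.int(seq_len(n), lens)),
           function(x) paste0(x, collapse = ""), "")[as.character(seq_len(n))]
  }
}

#' Generate random template molecules
#'
#' Template sequences are i.i.d. uniform over `{A, C, G, T}`; at typical
#' lengths the chance of two templates colliding is negligible
#' (about `choose(n, 2) / 4^length`), so template count is the ground-truth
#' distinct-molecule count.  Deterministic given the seed.
#'
#' @param n Number of templates (>= 0).
#' @param lengthRange Two-element integer range of template lengths
#'   (inclusive); lengths drawn uniformly.
#' @param paired Generate two mates per template?
#' @param seed Integer RNG seed.
#' @return Data frame with `template_id`, `seq1` and, if paired, `seq2`.
#' @export
generateTemplates <- function(n, lengthRange = c(100L, 100L), paired = FALSE,
                              seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0)
    fqStop("usage_error", "template count must be >= 0")
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || any(is.na(lengthRange)) ||
      lengthRange[1L] > lengthRange[2L] || lengthRange[1L] < 1L)
    fqStop("usage_error", "invalid length range")
  n <- as.integer(n)
  withSeed(seed, {
    drawLens <- function() {
      if (lengthRange[1L] == lengthRange[2L]) rep.int(lengthRange[1L], n)
      else sample(seq.int(lengthRange[1L], lengthRange[2L]), n, replace = TRUE)
    }
    out <- data.frame(template_id = sprintf("t%06d", seq_len(n)),
                      seq1 = randomSeqs(drawLens()))
    if (paired) out$seq2 <- randomSeqs(drawLens())
    if (!n) {
      out <- data.frame(template_id = character(0), seq1 = character(0))
      if (paired) out$seq2 <- character(0)
    }
    out
  })
}

#' Tail-biased substitution error model
#'
#' Per-base substitution rates are 0 over the first `tailStart` fraction of
#' positions and rise linearly to `maxRate` at the 3' end, emulating the
#' enrichment of sequencing errors near read ends.  With `maxRate = 0`
#' copies are exact.  Substitution-only (no indels): this matches what a
#' Hamming-distance comparison can express.
#'
#' @param maxRate Substitution probability at the final base, in `[0, 1]`.
#' @param tailStart Fraction of the read that is error-free, in `[0, 1]`.
#' @return An error-model object used by [amplifyTemplates()].
#' @export
tailErrorModel <- function(maxRate = 0.02, tailStart = 0.8) {
  if (maxRate < 0 || maxRate > 1 || tailStart < 0 || tailStart > 1)
    fqStop("usage_error", "error-model rates must lie in [0, 1]")
  structure(list(maxRate = maxRate, tailStart = tailStart),
            class = "fq_error_model")
}

errorRates <- function(model, L) {
  r <- numeric(L)
  i0 <- floor(model$tailStart * L)
  if (model$maxRate > 0 && L > i0) {
    j <- seq.int(i0 + 1L, L)
    r[j] <- model$maxRate * (j - i0) / (L - i0)
  }
  r
}

# Apply tail-biased substitutions to a vector of sequences; returns mutated
# sequences and the per-read substitution count.
mutateTails <- function(seqs, model) {
  n <- length(seqs)
  nsub <- integer(n)
  if (!n || model$maxRate == 0)
    return(list(seqs = seqs, nsub = nsub))
  out <- seqs
  for (g in split(seq_len(n), nchar(seqs))) {
    L <- nchar(seqs[g[1L]])
    if (L == 0L) next
    r <- errorRates(model, L)
    if (all(r == 0)) next
    m <- length(g)
    hit <- which(matrix(stats::runif(m * L), m, L) <
                   matrix(r, m, L, byrow = TRUE), arr.ind = TRUE)
    if (!nrow(hit)) next
    ch <- matrix(unlist(strsplit(seqs[g], "", fixed = TRUE),
                        use.names = FALSE), nrow = m, byrow = TRUE)
    orig <- ch[hit]
    # substitute with one of the three other bases, uniformly
    ch[hit] <- BASES[(match(orig, BASES) - 1L +
                        sample.int(3L, nrow(hit), replace = TRUE)) %% 4L + 1L]
    out[g] <- do.call(paste0, asplit(ch, 2L))
    nsub[g] <- tabulate(hit[, 1L], m)
  }
  list(seqs = out, nsub = nsub)
}

truncateTails <- function(seqs, truncationRange) {
  n <- length(seqs)
  if (!n) return(seqs)
  lens <- nchar(seqs)
  trims <- sample(seq.int(truncationRange[1L], truncationRange[2L]), n,
                  replace = TRUE)
  if (any(trims >= lens))
    fqStop("usage_error", "truncation longer than read")
  substr(seqs, 1L, lens - trims)
}

#' Amplify templates into a read library with a truth manifest
#'
#' Emits, per template, one original read plus `copies` PCR copies.  Each
#' copy is either 3'-truncated (with probability `truncationFraction`; the
#' truncated length is drawn uniformly from `truncationRange`, making it a
#' loose-mode prefix duplicate) or passed through the substitution error
#' model (class `tail_error_copy` when at least one substitution landed,
#' `exact_pcr_copy` otherwise).  For paired templates truncation and errors
#' are applied to each mate independently.  The manifest records every read's
#' template and class.
#'
#' @param templates Output of [generateTemplates()].
#' @param copies PCR copies per template in addition to the original: a
#'   single integer (>= 1), a vector of per-template counts, or a
#'   `function(n)` returning one.
#' @param errorModel A [tailErrorModel()].
#' @param truncationFraction Probability that a copy is truncated instead of
#'   error-modelled, in `[0, 1]`.
#' @param truncationRange Two-element range of 3' bases to trim.
#' @param seed Integer RNG seed.
#' @return A list with `reads` (unit frame without index, in generation
#'   order: originals first) and `manifest` (data frame `read_id`,
#'   `template_id`, `class`).
#' @export
amplifyTemplates <- function(templates, copies = 4L,
                             errorModel = tailErrorModel(0),
                             truncationFraction = 0,
                             truncationRange = c(5L, 20L), seed = 1L) {
  n <- nrow(templates)
  paired <- "seq2" %in% names(templates)
  if (is.function(copies)) copies <- copies(n)
  copies <- as.integer(rep_len(copies, n))
  if (n && (any(is.na(copies)) || any(copies < 1L)))
    fqStop("usage_error", "copies must be >= 1 per template")
  if (truncationFraction < 0 || truncationFraction > 1)
    fqStop("usage_error", "truncationFraction must lie in [0, 1]")
  truncationRange <- as.integer(truncationRange)
  if (length(truncationRange) != 2L || any(truncationRange < 1L) ||
      truncationRange[1L] > truncationRange[2L])
    fqStop("usage_error", "invalid truncation range")

  withSeed(seed, {
    tidx <- rep.int(seq_len(n), copies)
    m <- length(tidx)
    truncated <- stats::runif(m) < truncationFraction
    processMate <- function(tseq) {
      s <- tseq[tidx]
      nsub <- integer(m)
      if (any(!truncated)) {
        mut <- mutateTails(s[!truncated], errorModel)
        s[!truncated] <- mut$seqs
        nsub[!truncated] <- mut$nsub
      }
      if (any(truncated))
        s[truncated] <- truncateTails(s[truncated], truncationRange)
      list(seqs = s, nsub = nsub)
    }
    m1 <- processMate(templates$seq1)
    m2 <- if (paired) processMate(templates$seq2)
    cls <- ifelse(truncated, "truncated_copy",
                  ifelse(m1$nsub + (if (paired) m2$nsub else 0L) > 0L,
                         "tail_error_copy", "exact_pcr_copy"))
    ids <- sprintf("read%07d", seq_len(n + m))
    reads <- data.frame(
      id1 = ids,
      comment1 = "",
      seq1 = c(templates$seq1, m1$seqs),
      qual1 = NA_character_)
    if (paired) {
      reads$id2 <- ids
      reads$comment2 <- ""
      reads$seq2 <- c(templates$seq2, m2$seqs)
      reads$qual2 <- NA_character_
    }
    manifest <- data.frame(
      read_id = ids,
      template_id = c(templates$template_id, templates$template_id[tidx]),
      class = c(rep("original", n), if (m) cls else character(0)))
    list(reads = reads, manifest = manifest)
  })
}

#' Write a synthetic library and its truth manifest to disk
#'
#' Shuffles the reads deterministically by `seed`, synthesizes constant
#' maximum qualities (`I`) for FASTQ output, writes the read file(s) and a
#' tab-separated manifest (`read_id`, `template_id`, `class`).
#'
#' @param reads,manifest Output of [amplifyTemplates()].
#' @param path1,path2 Output read paths (`path2` only for paired reads).
#' @param manifestPath Output manifest path (default: `path1` +
#'   `".manifest.tsv"`).
#' @param format `"fastq"` or `"fasta"`.
#' @param compression As in [recordWriter()].
#' @param seed Integer seed for the shuffle.
#' @return Named character vector of the written paths.
#' @export
emitDataset <- function(reads, manifest, path1, path2 = NULL,
                        manifestPath = paste0(path1, ".manifest.tsv"),
                        format = "fastq", compression = "auto", seed = 1L) {
  paired <- isPairedUnits(reads)
  if (paired && is.null(path2))
    fqStop("usage_error", "paired reads need two output paths")
  o <- withSeed(seed, sample.int(nrow(reads)))
  reads <- reads[o, , drop = FALSE]
  if (format == "fastq") {
    reads$qual1 <- strrep("I", nchar(reads$seq1))
    if (paired) reads$qual2 <- strrep("I", nchar(reads$seq2))
  } else {
    reads$qual1 <- NA_character_
    if (paired) reads$qual2 <- NA_character_
  }
  reads$index <- seq_len(nrow(reads)) - 1L
  writeUnits(reads, path1, path2, format = format, compression = compression)
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(path1 = path1, path2 = if (paired) path2,
    manifest = manifestPath)
}

#' One-call synthetic library
#'
#' Convenience wrapper chaining [generateTemplates()], [amplifyTemplates()]
#' and [emitDataset()].  `readsPerTemplate` counts total reads per template
#' (original included), so the expected duplicate percentage under exact
#' copying is `100 * (readsPerTemplate - 1) / readsPerTemplate`.
#'
#' @param path1,path2 Output read paths.
#' @param templates Number of template molecules.
#' @param readsPerTemplate Total reads per template (>= 2).
#' @param lengthRange,paired,seed As in [generateTemplates()].
#' @param errorRate `maxRate` of the [tailErrorModel()].
#' @param truncationFraction,truncationRange As in [amplifyTemplates()].
#' @param format,compression,manifestPath As in [emitDataset()].
#' @return Named character vector of written paths, with the manifest data
#'   frame attached as attribute `"manifest"`.
#' @export
synthesizeLibrary <- function(path1, path2 = NULL, templates = 100L,
                              readsPerTemplate = 5L,
                              lengthRange = c(100L, 100L), paired = !is.null(path2),
                              errorRate = 0, truncationFraction = 0,
                              truncationRange = c(5L, 20L), seed = 1L,
                              format = "fastq", compression = "auto",
                              manifestPath = paste0(path1, ".manifest.tsv")) {
  if (readsPerTemplate < 2L)
    fqStop("usage_error", "readsPerTemplate must be >= 2")
  tpl <- generateTemplates(templates, lengthRange, paired, seed = seed)
  amp <- amplifyTemplates(tpl, copies = readsPerTemplate - 1L,
                          errorModel = tailErrorModel(errorRate),
                          truncationFraction = truncationFraction,
                          truncationRange = truncationRange,
                          seed = seed + 1L)
  paths <- emitDataset(amp$reads, amp$manifest, path1, path2,
                       manifestPath = manifestPath, format = format,
                       compression = compression, seed = seed + 2L)
  attr(paths, "manifest") <- amp$manifest
  paths
}
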