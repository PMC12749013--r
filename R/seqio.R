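# Streaming FASTQ/FASTA readers and writers, plain or gzip, single-end and
# positionally synchronized paired-end.
#
# Record batches are data frames with columns id, comment, sequence, quality
# (quality is NA for FASTA).  "Unit" frames carry one deduplication unit per
# row: index (0-based input position), id1/comment1/seq1/qual1 and, for
# paired-end data, id2/comment2/seq2/qual2.  Identifiers, sequences and
# qualities pass through every operation byte-for-byte.

#' Detect gzip compression by magic bytes
#'
#' @param path Path to an existing file.
#' @return `"gzip"` if the file starts with the RFC 1952 magic bytes
#'   `0x1F 0x8B`, otherwise `"none"` (including for empty files).
#' @examples
#' f <- tempfile(); writeLines("@r1", f)
#' detectCompression(f)
#' @export
detectCompression <- function(path) {
  if (!file.exists(path))
    fqStop("io_error", "cannot read '%s': no such file", path)
  sz <- file.info(path)$size
  if (is.na(sz)) fqStop("io_error", "cannot stat '%s'", path)
  if (sz < 2) return("none")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    "gzip" else "none"
}

resolveCompression <- function(path, compression, forWrite = FALSE) {
  compression <- match.arg(compression, c("auto", "none", "gzip"))
  if (compression != "auto") return(compression)
  if (forWrite) {
    if (grepl("\\.gz$", path, ignore.case = TRUE)) "gzip" else "none"
  } else {
    detectCompression(path)
  }
}

resolveFormat <- function(path, format, compression = "auto") {
  format <- match.arg(format, c("auto", "fastq", "fasta"))
  if (format != "auto") return(format)
  base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("fa", "fasta", "fna", "ffn", "frn", "faa")) return("fasta")
  if (ext %in% c("fq", "fastq")) return("fastq")
  # fall back to sniffing the first byte of the (decompressed) stream
  if (file.exists(path) && file.info(path)$size > 0) {
    con <- openInputConn(path, resolveCompression(path, "auto"))
    on.exit(close(con))
    first <- readLines(con, 1L, warn = FALSE)
    if (length(first)) {
      if (startsWith(first, ">")) return("fasta")
      if (startsWith(first, "@")) return("fastq")
    }
  }
  "fastq"
}

openInputConn <- function(path, compression) {
  if (!file.exists(path))
    fqStop("io_error", "cannot read '%s': no such file", path)
  con <- tryCatch(
    if (compression == "gzip") gzfile(path, "rt") else file(path, "rt"),
    error = function(e) fqStop("io_error", "cannot open '%s': %s", path,
                               conditionMessage(e)))
  con
}

splitHeader <- function(lines, marker, ordinalStart) {
  bad <- !startsWith(lines, marker)
  if (any(bad)) {
    i <- which(bad)[1L]
    fqStop("malformed_input",
           "malformed record %d: header does not start with '%s'",
           ordinalStart + i - 1L, marker)
  }
  h <- substring(lines, 2L)
  at <- regexpr("[ \t]", h)
  hasC <- at > 0L
  id <- ifelse(hasC, substr(h, 1L, at - 1L), h)
  comment <- ifelse(hasC, substring(h, at + 1L), "")
  list(id = id, comment = comment)
}

stripCR <- function(lines) {
  if (length(lines) && any(endsWith(utils::head(lines, 50L), "\r")))
    sub("\r$", "", lines)
  else lines
}

parseFastqLines <- function(lines, ordinalStart) {
  n <- length(lines)
  if (n %% 4L != 0L)
    fqStop("malformed_input",
           "truncated FASTQ record %d: %d trailing line(s)",
           ordinalStart + n %/% 4L, n %% 4L)
  idx <- seq.int(1L, n, by = 4L)
  hdr <- splitHeader(lines[idx], "@", ordinalStart)
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  badPlus <- !startsWith(plus, "+")
  if (any(badPlus))
    fqStop("malformed_input",
           "malformed record %d: separator line does not start with '+'",
           ordinalStart + which(badPlus)[1L] - 1L)
  badLen <- nchar(seqs, type = "bytes") != nchar(quals, type = "bytes")
  if (any(badLen))
    fqStop("malformed_input",
           "malformed record %d: sequence and quality lengths differ",
           ordinalStart + which(badLen)[1L] - 1L)
  data.frame(id = hdr$id, comment = hdr$comment, sequence = seqs,
             quality = quals)
}

parseFastaLines <- function(lines, ordinalStart) {
  if (!length(lines))
    return(data.frame(id = character(), comment = character(),
                      sequence = character(), quality = character()))
  isH <- startsWith(lines, ">")
  if (!isH[1L])
    fqStop("malformed_input",
           "malformed record %d: expected FASTA header line", ordinalStart)
  hdr <- splitHeader(lines[isH], ">", ordinalStart)
  nrec <- sum(isH)
  seqs <- character(nrec)
  grp <- cumsum(isH)[!isH]
  if (length(grp)) {
    sp <- split(lines[!isH], grp)
    seqs[as.integer(names(sp))] <-
      vapply(sp, function(x) paste0(x, collapse = ""), "")
  }
  data.frame(id = hdr$id, comment = hdr$comment, sequence = seqs,
             quality = NA_character_)
}

#' Stream sequence records from a FASTQ or FASTA file
#'
#' `recordStreamer()` opens `path` and returns a zero-argument function that
#' yields successive batches of records as data frames with columns
#' `id`, `comment`, `sequence`, `quality` (`NA` for FASTA), then `NULL` at
#' end of file.  FASTQ is parsed as strict 4-line records; FASTA sequences
#' may span multiple lines and are concatenated.  Trailing CR characters
#' (CRLF input) are stripped.  Truncated FASTQ records and sequence/quality
#' length mismatches raise a malformed-input error naming the record
#' ordinal.
#'
#' `parseRecords()` drains the whole file into one data frame.
#'
#' @param path Input file (plain or gzip-compressed).
#' @param format `"auto"` (by extension, then content sniffing), `"fastq"`
#'   or `"fasta"`.
#' @param compression `"auto"` (by magic bytes), `"none"` or `"gzip"`.
#' @param chunkSize Records per batch.
#' @return A streamer function, or for `parseRecords()` a record data frame.
#' @examples
#' f <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' parseRecords(f)
#' @export
recordStreamer <- function(path, format = "auto", compression = "auto",
                           chunkSize = 40000L) {
  compression <- resolveCompression(path, compression)
  format <- resolveFormat(path, format, compression)
  con <- openInputConn(path, compression)
  open <- TRUE
  consumed <- 0L
  pending <- character(0)   # FASTA: lines of a possibly incomplete tail record
  finish <- function() {
    if (open) { close(con); open <<- FALSE }
  }
  failClosing <- function(e) {
    finish()
    stop(e)
  }
  if (format == "fastq") {
    streamer <- function() {
      if (!open) return(NULL)
      lines <- stripCR(readLines(con, chunkSize * 4L, warn = FALSE))
      if (!length(lines)) { finish(); return(NULL) }
      out <- tryCatch(parseFastqLines(lines, consumed + 1L),
                      error = failClosing)
      consumed <<- consumed + nrow(out)
      if (length(lines) < chunkSize * 4L) finish()
      out
    }
  } else {
    streamer <- function() {
      if (!open && !length(pending)) return(NULL)
      repeat {
        lines <- if (open) readLines(con, chunkSize * 2L, warn = FALSE)
                 else character(0)
        eof <- length(lines) < chunkSize * 2L
        pending <<- c(pending, stripCR(lines))
        if (eof) { finish(); break }
        # keep the (possibly incomplete) final record buffered
        hIdx <- which(startsWith(pending, ">"))
        if (length(hIdx) >= 2L) break
      }
      if (!length(pending)) return(NULL)
      hIdx <- which(startsWith(pending, ">"))
      if (open && length(hIdx) >= 2L) {
        cut <- hIdx[length(hIdx)]
        block <- pending[seq_len(cut - 1L)]
        pending <<- pending[cut:length(pending)]
      } else {
        block <- pending
        pending <<- character(0)
      }
      out <- tryCatch(parseFastaLines(block, consumed + 1L),
                      error = failClosing)
      consumed <<- consumed + nrow(out)
      out
    }
  }
  streamer
}

#' @rdname recordStreamer
#' @export
parseRecords <- function(path, format = "auto", compression = "auto") {
  s <- recordStreamer(path, format, compression)
  out <- collectUnits(s)
  if (!nrow(out))
    out <- data.frame(id = character(), comment = character(),
                      sequence = character(), quality = character())
  out
}

formatRecordLines <- function(records, format) {
  hdr <- paste0(if (format == "fastq") "@" else ">", records$id,
                ifelse(records$comment == "" | is.na(records$comment), "",
                       paste0(" ", records$comment)))
  if (format == "fastq") {
    qual <- records$quality
    if (anyNA(qual))
      fqStop("contract_violation",
             "FASTQ output requires a quality string for every record")
    as.vector(rbind(hdr, records$sequence, "+", qual))
  } else {
    as.vector(rbind(hdr, records$sequence))
  }
}

#' Write sequence records to a FASTQ or FASTA file
#'
#' `recordWriter()` returns a sink with `$write(records)` and `$close()`
#' (which returns the record count); `writeRecords()` writes a whole record
#' data frame at once.  Output uses LF line endings and is gzip-compressed
#' when requested (or when the path ends in `.gz` under `compression =
#' "auto"`).  Fields are written verbatim, so a write/parse round trip
#' reproduces ids, comments, sequences and qualities exactly.
#'
#' @param records Record data frame (`id`, `comment`, `sequence`, `quality`).
#' @param path Output path.
#' @param format `"fastq"` or `"fasta"` (`"auto"`: by output extension, else
#'   FASTQ when qualities are present).
#' @param compression `"auto"`, `"none"` or `"gzip"`.
#' @return `writeRecords()`: the number of records written, invisibly a
#'   visible count.
#' @export
recordWriter <- function(path, format = "fastq", compression = "auto") {
  compression <- resolveCompression(path, compression, forWrite = TRUE)
  format <- match.arg(format, c("fastq", "fasta"))
  con <- tryCatch(
    if (compression == "gzip") gzfile(path, "wt") else file(path, "wt"),
    error = function(e) fqStop("io_error", "cannot open '%s' for writing: %s",
                               path, conditionMessage(e)))
  count <- 0L
  list(
    write = function(records) {
      if (!nrow(records)) return(invisible(0L))
      writeLines(formatRecordLines(records, format), con)
      count <<- count + nrow(records)
      invisible(nrow(records))
    },
    close = function() { close(con); count }
  )
}

#' @rdname recordWriter
#' @export
writeRecords <- function(records, path, format = "auto", compression = "auto") {
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fa", "fasta", "fna", "ffn", "frn", "faa"))
      "fasta"
    else if (ext %in% c("fq", "fastq")) "fastq"
    else if (nrow(records) && anyNA(records$quality)) "fasta" else "fastq"
  }
  w <- recordWriter(path, format, compression)
  ok <- FALSE
  on.exit(if (!ok) try(w$close(), silent = TRUE))
  w$write(records)
  ok <- TRUE
  w$close()
}

recordsToUnits <- function(records, startIndex, mate = 1L) {
  cols <- list(records$id, records$comment, records$sequence, records$quality)
  names(cols) <- paste0(c("id", "comment", "seq", "qual"), mate)
  if (mate == 1L)
    cols <- c(list(index = seq.int(startIndex, length.out = nrow(records))),
              cols)
  as.data.frame(cols)
}

#' Stream deduplication units from one or two read files
#'
#' Single-end units wrap one record; paired-end units pair the i-th record of
#' `pathL` with the i-th record of `pathR` (strict positional pairing, no ID
#' matching).  Every unit carries `index`, its 0-based position in the input
#' stream.  Files with unequal record counts raise a synchronization error
#' reporting both counts.
#'
#' @param pathL,pathR Input paths; `pathR = NULL` for single-end.
#' @param format,compression,chunkSize As in [recordStreamer()].
#' @return `pairedReader()` / `unitReader()`: a streamer of unit frames.
#'   `readUnits()`: one unit frame for the whole input.
#' @export
unitReader <- function(pathL, pathR = NULL, format = "auto",
                       compression = "auto", chunkSize = 40000L) {
  sL <- recordStreamer(pathL, format, compression, chunkSize)
  sR <- if (!is.null(pathR)) recordStreamer(pathR, format, compression, chunkSize)
  count <- 0L
  if (is.null(sR)) {
    return(function() {
      b <- sL()
      if (is.null(b)) return(NULL)
      out <- recordsToUnits(b, count)
      count <<- count + nrow(b)
      out
    })
  }
  drain <- function(s, n) {
    repeat {
      b <- s()
      if (is.null(b)) return(n)
      n <- n + nrow(b)
    }
  }
  function() {
    a <- sL()
    b <- sR()
    na <- if (is.null(a)) 0L else nrow(a)
    nb <- if (is.null(b)) 0L else nrow(b)
    if (na != nb) {
      totalA <- drain(sL, count + na)
      totalB <- drain(sR, count + nb)
      fqStop("sync_error",
             "paired inputs are out of sync: %d vs %d records",
             totalA, totalB, data = list(left = totalA, right = totalB))
    }
    if (na == 0L) return(NULL)
    out <- cbind(recordsToUnits(a, count), recordsToUnits(b, 0L, mate = 2L))
    count <<- count + na
    out
  }
}

#' @rdname unitReader
#' @export
pairedReader <- function(pathL, pathR, format = "auto", compression = "auto",
                         chunkSize = 40000L) {
  unitReader(pathL, pathR, format, compression, chunkSize)
}

#' @rdname unitReader
#' @export
readUnits <- function(pathL, pathR = NULL, format = "auto",
                      compression = "auto") {
  collectUnits(unitReader(pathL, pathR, format, compression))
}

unitsToRecords <- function(units, mate = 1L) {
  p <- function(f) units[[paste0(f, mate)]]
  data.frame(id = p("id"), comment = p("comment"), sequence = p("seq"),
             quality = p("qual"))
}

#' Write deduplication units to one or two read files
#'
#' Left mates go to `pathL`, right mates (required for every unit, forbidden
#' for none) to `pathR`, in matching order, so paired outputs stay
#' positionally synchronized.
#'
#' @param units A unit frame or a unit streamer.
#' @param pathL,pathR Output paths; `pathR = NULL` for single-end units.
#' @param format,compression As in [recordWriter()].
#' @return Invisibly, the per-file record counts (`countL`, `countR`).
#' @export
writeUnits <- function(units, pathL, pathR = NULL, format = "fastq",
                       compression = "auto") {
  stream <- if (is.function(units)) units else unitStreamer(units)
  wL <- recordWriter(pathL, format, compression)
  wR <- if (!is.null(pathR)) recordWriter(pathR, format, compression)
  ok <- FALSE
  on.exit(if (!ok) {
    try(wL$close(), silent = TRUE)
    if (!is.null(wR)) try(wR$close(), silent = TRUE)
  })
  repeat {
    b <- stream()
    if (is.null(b)) break
    if (!nrow(b)) next
    paired <- isPairedUnits(b)
    if (!is.null(wR) && !paired)
      fqStop("contract_violation", "unit is missing its right mate")
    if (is.null(wR) && paired)
      fqStop("usage_error", "paired units need two output paths")
    wL$write(unitsToRecords(b, 1L))
    if (!is.null(wR)) wR$write(unitsToRecords(b, 2L))
  }
  ok <- TRUE
  cL <- wL$close()
  cR <- if (!is.null(wR)) wR$close() else NULL
  invisible(c(countL = cL, countR = cR))
}

#' @rdname writeUnits
#' @export
pairedWriter <- function(units, pathL, pathR, format = "fastq",
                         compression = "auto") {
  counts <- writeUnits(units, pathL, pathR, format, compression)
  invisible(counts)
}
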