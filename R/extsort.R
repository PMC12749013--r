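# Memory-budgeted external merge sort of deduplication units.
#
# Units are buffered until the summed footprint would exceed the budget,
# sorted by (key, index) and flushed as a "run": a private line-oriented
# temporary file with fields joined by the 0x1F unit separator.  Runs are
# then k-way merged back into one lazily produced sorted stream; when more
# runs exist than may be open at once they are merged in cascades, with
# consumed runs deleted immediately so live temporary bytes stay bounded.

FIELD_SEP <- "\x1f"

#' Approximate in-memory footprint of deduplication units
#'
#' The budget accounting used by the external sort: the byte length of every
#' text field of a unit plus a fixed overhead constant of 96 bytes per mate
#' (an estimate of container overhead; the contract is bounded,
#' parameterizable buffering, not byte-exact RSS).
#'
#' @param units A unit frame.
#' @return Numeric vector of per-unit byte footprints.
#' @examples
#' u <- data.frame(index = 0L, id1 = "r", comment1 = "", seq1 = "ACGT",
#'                 qual1 = "IIII")
#' unitFootprint(u)  # 9 + 96
#' @export
unitFootprint <- function(units) {
  f <- ncharBytes(units$id1) + ncharBytes(units$comment1) +
    ncharBytes(units$seq1) + ncharBytes(units$qual1) + 96
  if (isPairedUnits(units))
    f <- f + ncharBytes(units$id2) + ncharBytes(units$comment2) +
      ncharBytes(units$seq2) + ncharBytes(units$qual2) + 96
  as.numeric(f)
}

serializeUnits <- function(units) {
  naBlank <- function(x) ifelse(is.na(x), "", x)
  if (isPairedUnits(units))
    paste(units$index, units$id1, units$comment1, units$seq1,
          naBlank(units$qual1), units$id2, units$comment2, units$seq2,
          naBlank(units$qual2), sep = FIELD_SEP)
  else
    paste(units$index, units$id1, units$comment1, units$seq1,
          naBlank(units$qual1), sep = FIELD_SEP)
}

deserializeUnits <- function(lines, paired, hasQual) {
  f <- data.table::tstrsplit(lines, FIELD_SEP, fixed = TRUE)
  nf <- if (paired) 9L else 5L
  if (length(f) < nf) {
    # trailing empty fields are dropped by the splitter; restore them
    f <- c(f, rep(list(rep("", length(lines))), nf - length(f)))
  }
  f <- lapply(f, function(x) { x[is.na(x)] <- ""; x })
  qual <- function(x) if (hasQual) x else rep(NA_character_, length(lines))
  out <- data.frame(index = as.integer(f[[1L]]), id1 = f[[2L]],
                    comment1 = f[[3L]], seq1 = f[[4L]], qual1 = qual(f[[5L]]))
  if (paired) {
    out$id2 <- f[[6L]]; out$comment2 <- f[[7L]]
    out$seq2 <- f[[8L]]; out$qual2 <- qual(f[[9L]])
  }
  out
}

newAcct <- function() {
  acct <- new.env(parent = emptyenv())
  acct$tempBytes <- 0
  acct$liveBytes <- 0
  acct$peakLiveBytes <- 0
  acct$inputBytes <- 0
  acct
}

acctAdd <- function(acct, bytes) {
  acct$tempBytes <- acct$tempBytes + bytes
  acct$liveBytes <- acct$liveBytes + bytes
  acct$peakLiveBytes <- max(acct$peakLiveBytes, acct$liveBytes)
}

writeRunFile <- function(units, tmpdir, acct) {
  path <- tempfile("run", tmpdir = tmpdir, fileext = ".run")
  con <- file(path, "wt")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) unlink(path)
  })
  writeLines(serializeUnits(units), con)
  ok <- TRUE
  close(con)
  on.exit()
  sz <- file.info(path)$size
  acctAdd(acct, sz)
  list(path = path, n_records = nrow(units), byte_size = sz,
       paired = isPairedUnits(units), hasQual = !anyNA(units$qual1),
       frame = NULL)
}

sortUnits <- function(units, keyFun) {
  o <- order(keyFun(units), units$index, method = "radix")
  out <- units[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build sorted runs from a unit stream under a memory budget
#'
#' Buffers units until adding the next one would push the summed
#' [unitFootprint()] beyond the budget, sorts the buffer by
#' `(keyFun(unit), index)` and writes it as one temporary run file; repeats
#' until the stream is exhausted.  If the whole input fits within the budget
#' the single run is kept in memory and no temporary file is written.
#'
#' @param stream A unit streamer (see [unitStreamer()]).
#' @param keyFun Vectorized function mapping a unit frame to character sort
#'   keys (byte order), e.g. [sortKey()].
#' @param budget A [memoryBudget()] or a byte count.
#' @param tmpdir Directory for temporary run files.
#' @param acct Internal accounting environment (optional).
#' @return List of run descriptors (path, n_records, byte_size), each run
#'   internally sorted.
#' @export
buildRuns <- function(stream, keyFun, budget, tmpdir = tempdir(),
                      acct = newAcct()) {
  bytes <- budgetBytes(budget)
  if (!dir.exists(tmpdir))
    fqStop("io_error", "tmpdir '%s' does not exist", tmpdir)
  runs <- list()
  buf <- list()
  bufFoot <- 0
  flush <- function() {
    units <- data.table::rbindlist(buf)
    data.table::setDF(units)
    runs[[length(runs) + 1L]] <<- writeRunFile(sortUnits(units, keyFun),
                                               tmpdir, acct)
    buf <<- list()
    bufFoot <<- 0
  }
  repeat {
    batch <- stream()
    if (is.null(batch)) break
    if (!nrow(batch)) next
    foot <- unitFootprint(batch)
    acct$inputBytes <- acct$inputBytes + sum(foot - 96 * (1 + isPairedUnits(batch)))
    while (nrow(batch)) {
      cum <- cumsum(foot)
      fit <- bufFoot + cum <= bytes
      take <- if (any(fit)) max(which(fit)) else 0L
      if (take == 0L) {
        if (bufFoot > 0) {
          flush()
          next
        }
        take <- 1L  # single unit larger than the budget: emit it alone
      }
      buf[[length(buf) + 1L]] <- batch[seq_len(take), , drop = FALSE]
      bufFoot <- bufFoot + cum[take]
      batch <- batch[-seq_len(take), , drop = FALSE]
      foot <- foot[-seq_len(take)]
    }
  }
  if (length(buf)) {
    if (!length(runs)) {
      # whole input fits in memory: one in-memory run, zero temp files
      units <- data.table::rbindlist(buf)
      data.table::setDF(units)
      units <- sortUnits(units, keyFun)
      runs <- list(list(path = NA_character_, n_records = nrow(units),
                        byte_size = 0, paired = isPairedUnits(units),
                        hasQual = !anyNA(units$qual1), frame = units))
    } else {
      flush()
    }
  }
  runs
}

# Per-run cursor over a run file or an in-memory run.
openRunCursor <- function(run, keyFun, chunkSize, acct) {
  st <- new.env(parent = emptyenv())
  st$fileDone <- FALSE
  st$buf <- NULL       # unit frame
  st$keys <- character(0)
  st$pos <- 0L         # cursor into in-memory frame
  st$run <- run
  if (is.na(run$path)) {
    st$con <- NULL
  } else {
    st$con <- file(run$path, "rt")
  }
  st$readMore <- function(n = chunkSize) {
    if (st$fileDone) return(FALSE)
    if (is.null(st$con)) {
      total <- nrow(st$run$frame)
      if (st$pos >= total) {
        st$fileDone <- TRUE
        return(FALSE)
      }
      take <- min(n, total - st$pos)
      chunk <- st$run$frame[(st$pos + 1L):(st$pos + take), , drop = FALSE]
      st$pos <- st$pos + take
      if (st$pos >= total) st$fileDone <- TRUE
    } else {
      lines <- readLines(st$con, n, warn = FALSE)
      if (!length(lines)) {
        st$fileDone <- TRUE
        close(st$con)
        st$con <- NULL
        acct$liveBytes <- acct$liveBytes - st$run$byte_size
        unlink(st$run$path)
        return(FALSE)
      }
      chunk <- deserializeUnits(lines, st$run$paired, st$run$hasQual)
    }
    st$buf <- if (is.null(st$buf)) chunk else {
      b <- data.table::rbindlist(list(st$buf, chunk))
      data.table::setDF(b)
      b
    }
    st$keys <- c(st$keys, keyFun(chunk))
    TRUE
  }
  st$destroy <- function() {
    if (!is.null(st$con)) {
      close(st$con)
      st$con <- NULL
    }
    if (!is.na(st$run$path) && file.exists(st$run$path)) {
      acct$liveBytes <- acct$liveBytes - st$run$byte_size
      unlink(st$run$path)
    }
    st$fileDone <- TRUE
    st$buf <- NULL
    st$keys <- character(0)
  }
  st
}

# Merge a set of sorted runs into a lazily produced, globally sorted stream.
# Emission rule: with bound = the byte-wise minimum over not-yet-exhausted
# runs of their last buffered key, all buffered records with key < bound are
# safe; records with key == bound are additionally safe from runs up to and
# including the first unexhausted run sitting at the bound (runs are built
# in input order, so run order is index order for equal keys).
streamMerge <- function(runs, keyFun, chunkSize, acct) {
  cursors <- lapply(runs, openRunCursor, keyFun = keyFun,
                    chunkSize = chunkSize, acct = acct)
  done <- FALSE
  function() {
    if (done) return(NULL)
    repeat {
      for (st in cursors)
        if (!st$fileDone && !length(st$keys)) st$readMore()
      pendingIdx <- which(vapply(cursors, function(st) !st$fileDone, NA))
      bufferedIdx <- which(vapply(cursors,
                                  function(st) length(st$keys) > 0L, NA))
      if (!length(bufferedIdx)) {
        done <- TRUE
        for (st in cursors) st$destroy()
        return(NULL)
      }
      if (!length(pendingIdx)) {
        # everything is buffered: emit the remainder in one sorted chunk
        parts <- lapply(cursors[bufferedIdx], function(st) st$buf)
        out <- data.table::rbindlist(parts)
        data.table::setDF(out)
        out <- sortUnits(out, keyFun)
        for (st in cursors) { st$buf <- NULL; st$keys <- character(0) }
        done <- TRUE
        return(out)
      }
      lastKeys <- vapply(cursors[pendingIdx],
                         function(st) st$keys[length(st$keys)], "")
      bound <- minKey(lastKeys)
      atBound <- pendingIdx[lastKeys == bound]
      eqCutoff <- min(atBound)  # runs <= this may emit records equal to bound
      parts <- list()
      for (i in bufferedIdx) {
        st <- cursors[[i]]
        lt <- str_lt_cpp(st$keys, bound)
        take <- sum(lt)
        if (i <= eqCutoff) take <- sum(lt | st$keys == bound)
        if (take > 0L) {
          parts[[length(parts) + 1L]] <-
            st$buf[seq_len(take), , drop = FALSE]
          if (take >= nrow(st$buf)) {
            st$buf <- NULL
            st$keys <- character(0)
          } else {
            st$buf <- st$buf[-seq_len(take), , drop = FALSE]
            st$keys <- st$keys[-seq_len(take)]
          }
        }
      }
      if (length(parts)) {
        out <- data.table::rbindlist(parts)
        data.table::setDF(out)
        return(sortUnits(out, keyFun))
      }
      # no progress: every buffered key sits at the bound in later runs;
      # pull more data from the runs that define the bound
      for (i in atBound) cursors[[i]]$readMore()
    }
  }
}

#' Merge sorted runs into one sorted unit stream
#'
#' Stable on key ties by ascending original index.  When more than
#' `maxOpenFiles` runs exist, groups are first merged into intermediate runs
#' (cascaded merge); consumed run files are deleted as soon as they are
#' exhausted.
#'
#' @param runs Run list from [buildRuns()].
#' @inheritParams buildRuns
#' @param maxOpenFiles Maximum runs merged at once.
#' @param chunkSize Records read per run per refill.
#' @return A streamer of globally sorted unit frames.
#' @export
kwayMerge <- function(runs, keyFun, maxOpenFiles = 128L, chunkSize = 20000L,
                      tmpdir = tempdir(), acct = newAcct()) {
  if (!length(runs)) return(function() NULL)
  if (maxOpenFiles < 2L) fqStop("usage_error", "maxOpenFiles must be >= 2")
  while (length(runs) > maxOpenFiles) {
    groups <- split(runs, ceiling(seq_along(runs) / maxOpenFiles))
    runs <- lapply(groups, function(g) {
      if (length(g) == 1L) return(g[[1L]])
      s <- streamMerge(g, keyFun, chunkSize, acct)
      mergeStreamToRun(s, tmpdir, acct)
    })
    names(runs) <- NULL
  }
  streamMerge(runs, keyFun, chunkSize, acct)
}

mergeStreamToRun <- function(stream, tmpdir, acct) {
  path <- tempfile("merge", tmpdir = tmpdir, fileext = ".run")
  con <- file(path, "wt")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) unlink(path)
  })
  n <- 0L
  paired <- FALSE
  hasQual <- TRUE
  repeat {
    b <- stream()
    if (is.null(b)) break
    if (!nrow(b)) next
    paired <- isPairedUnits(b)
    hasQual <- !anyNA(b$qual1)
    writeLines(serializeUnits(b), con)
    n <- n + nrow(b)
  }
  ok <- TRUE
  close(con)
  on.exit()
  sz <- file.info(path)$size
  acctAdd(acct, sz)
  list(path = path, n_records = n, byte_size = sz, paired = paired,
       hasQual = hasQual, frame = NULL)
}

#' Externally sort a unit stream by a key under a memory budget
#'
#' Composition of [buildRuns()] and [kwayMerge()].  The output is the input
#' permuted into `(keyFun(unit), index)` order; because the index breaks
#' every tie the output is identical record-for-record for any budget.
#'
#' @inheritParams buildRuns
#' @param maxOpenFiles,chunkSize Passed to [kwayMerge()].
#' @return A streamer of sorted unit frames, with the accounting environment
#'   attached as attribute `"acct"` (temporary bytes written, peak live
#'   temporary bytes, serialized input bytes).
#' @examples
#' u <- data.frame(index = 0:2, id1 = c("a", "b", "c"),
#'                 comment1 = "", seq1 = c("TT", "AA", "GG"),
#'                 qual1 = c("II", "II", "II"))
#' s <- externalSort(unitStreamer(u), sortKey, memoryBudget(16))
#' collectUnits(s)$seq1
#' @export
externalSort <- function(stream, keyFun, budget = memoryBudget(),
                         tmpdir = tempdir(), maxOpenFiles = 128L,
                         chunkSize = 20000L) {
  acct <- newAcct()
  runs <- buildRuns(stream, keyFun, budget, tmpdir, acct)
  out <- kwayMerge(runs, keyFun, maxOpenFiles, chunkSize, tmpdir, acct)
  attr(out, "acct") <- acct
  out
}
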