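# Internal helpers: classed conditions, seeded evaluation, streamer plumbing.

fqStop <- function(class, fmt, ..., data = NULL) {
  cond <- errorCondition(
    sprintf(fmt, ...),
    class = c(paste0("fqdedup_", class), "fqdedup_error")
  )
  if (!is.null(data)) cond$data <- data
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporary RNG state so generators are reproducible
# without clobbering the caller's stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Stream an in-memory unit table in fixed-size chunks
#'
#' Streamers are the package's lazy-sequence convention: zero-argument
#' functions returning the next batch of units as a data frame, or `NULL`
#' at end of stream.  `unitStreamer()` adapts an in-memory table to that
#' contract; `collectUnits()` drains a streamer back into one table.
#'
#' @param units A unit data frame (see [readUnits()]).
#' @param chunkSize Rows per batch.
#' @return `unitStreamer()`: a function() yielding data frames then `NULL`.
#' @export
unitStreamer <- function(units, chunkSize = 40000L) {
  stopifnot(is.data.frame(units))
  pos <- 0L
  n <- nrow(units)
  function() {
    if (pos >= n) return(NULL)
    take <- min(chunkSize, n - pos)
    out <- units[(pos + 1L):(pos + take), , drop = FALSE]
    pos <<- pos + take
    rownames(out) <- NULL
    out
  }
}

#' @rdname unitStreamer
#' @param stream A streamer function.
#' @return `collectUnits()`: a single data frame (zero rows if the stream is
#'   empty).
#' @export
collectUnits <- function(stream) {
  parts <- list()
  i <- 0L
  repeat {
    b <- stream()
    if (is.null(b)) break
    if (nrow(b)) {
      i <- i + 1L
      parts[[i]] <- b
    }
  }
  if (!length(parts)) return(data.frame())
  out <- data.table::rbindlist(parts)
  data.table::setDF(out)
  rownames(out) <- NULL
  out
}

# TRUE when a unit frame carries paired mates.
isPairedUnits <- function(units) "seq2" %in% names(units)

ncharBytes <- function(x) {
  n <- nchar(x, type = "bytes")
  n[is.na(x)] <- 0L
  n
}

# Byte-wise minimum of a character vector (C-locale order).
minKey <- function(x) x[order(x, method = "radix")[1L]]
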