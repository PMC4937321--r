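# Orchestration: parse -> adapt -> serialize -> compress -> write, and the
# reverse; plus sorted-key sampling and bisection range queries.
#
# Chunking contract: a chunk is a contiguous run of records (never split),
# compressed independently per stream.  Chunks may be compressed by several
# workers but are committed in input order, so container bytes are a pure
# function of (input, schema, job config) regardless of worker count.

#' Compare two sort keys
#'
#' A key is a list of scalars (numbers and/or strings), compared
#' lexicographically; string components compare bytewise, a missing
#' component sorts before any present one.
#'
#' @param a,b keys.
#' @return negative / zero / positive, like a C comparator.
#' @export
compareKeys <- function(a, b) {
  if (!is.list(a)) a <- as.list(a)
  if (!is.list(b)) b <- as.list(b)
  for (i in seq_len(min(length(a), length(b)))) {
    x <- a[[i]]; y <- b[[i]]
    if (is.character(x) || is.character(y)) {
      x <- as.character(x); y <- as.character(y)
      if (x != y) {
        rx <- charToRaw(x); ry <- charToRaw(y)
        m <- min(length(rx), length(ry))
        if (m > 0) {
          d <- which(rx[seq_len(m)] != ry[seq_len(m)])
          if (length(d))
            return(if (rx[d[1]] < ry[d[1]]) -1L else 1L)
        }
        return(if (length(rx) < length(ry)) -1L else 1L)
      }
    } else {
      if (x < y) return(-1L)
      if (x > y) return(1L)
    }
  }
  length(a) - length(b)
}

# bisection over nondecreasing first-of-chunk key samples.
# Returns 0-based half-open chunk interval [first, lastExcl) with a
# "comparisons" attribute; <= 2*ceil(log2(n)) + 2 key comparisons.
.locateBisect <- function(samples, lo, hi) {
  n <- length(samples)
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  le <- function(key, bound) {
    counter$k <- counter$k + 1L
    compareKeys(key, bound) <= 0L
  }
  # count of samples[from..n] <= key
  upperCount <- function(key, from) {
    l <- from; r <- n + 1L
    while (l < r) {
      m <- (l + r) %/% 2L
      if (le(samples[[m]], key)) l <- m + 1L else r <- m
    }
    l - from
  }
  first <- if (n >= 2) upperCount(lo, 2L) else 0L
  lastExcl <- upperCount(hi, 1L)
  if (lastExcl < first) lastExcl <- first
  structure(c(first = first, lastExcl = lastExcl),
            comparisons = counter$k)
}

#' Locate the chunk interval that can contain a key range
#'
#' Bisects over the dataset's sampled first-of-chunk keys and returns the
#' minimal 0-based half-open chunk interval whose records can hold keys in
#' `[lo, hi]` (inclusive).  Uses at most `2*ceil(log2(nChunks)) + 2` key
#' comparisons (available as the `comparisons` attribute).
#'
#' @param descriptor a sorted dataset's [DatasetDescriptor-class].
#' @param lo,hi keys with `lo <= hi`.
#' @return `c(first, lastExcl)` (0-based, half-open) with attribute
#'   `comparisons`.
#' @export
locateChunkRange <- function(descriptor, lo, hi) {
  ks <- descriptor@keySamples
  if (is.null(ks))
    stopData("dataset '%s' is not sorted (no key samples)", descriptor@name)
  if (compareKeys(lo, hi) > 0)
    stopUsage("empty key range: lo > hi")
  .locateBisect(ks, lo, hi)
}

# ---------------------------------------------------------------------------
# compression
# ---------------------------------------------------------------------------

.chunkBounds <- function(n, per) {
  if (n == 0) return(list())
  starts <- seq.int(1L, n, by = per)
  lapply(seq_along(starts), function(i)
    c(starts[i], min(starts[i] + per - 1, n)))
}

.applyAdaptors <- function(records, ords, adaptors) {
  for (ad in adaptors)
    records <- lapply(seq_along(records),
                      function(j) ad(records[[j]], ords[j]))
  records
}

#' Compress a dataset into a container
#'
#' Runs the full compressor path: the parser turns source text into a
#' header plus record values; records are chunked (`job@chunkRecords` per
#' chunk), adaptors applied in order, each chunk serialized into per-stream
#' payloads, each payload compressed with its stream's codec and appended
#' to the stream; finally blocks are allocated and written and the dataset
#' descriptor (with per-chunk index and, for keyed jobs, first-key samples)
#' enters the catalog.  If any step fails, no dataset is cataloged and all
#' reserved blocks are released.
#'
#' @param handle container handle.
#' @param name dataset name.
#' @param text input file content (single string, LF line endings).
#' @param parser `function(text) -> list(header=, records=)`, e.g.
#'   [parseFastq()] or [parseSam()].
#' @param job a [compressionJob()].
#' @return the stored [DatasetDescriptor-class], invisibly.
#' @export
compressDataset <- function(handle, name, text, parser, job) {
  stopifnot(is(job, "CompressionJob"))
  parsed <- parser(text)
  records <- parsed$records
  n <- length(records)
  plan <- job@plan
  paths <- streamPaths(plan)

  keySamplesAll <- NULL
  if (!is.null(job@keyFn) && n > 0) {
    keys <- lapply(records, job@keyFn)
    for (i in seq_len(n - 1))
      if (compareKeys(keys[[i]], keys[[i + 1]]) > 0L)
        stopData("records not sorted by key: violation at record %d", i + 1)
    keySamplesAll <- keys
  }

  bounds <- .chunkBounds(n, job@chunkRecords)
  compressOne <- function(b) {
    rs <- records[b[1]:b[2]]
    rs <- .applyAdaptors(rs, b[1]:b[2], job@adaptors)
    chunk <- serializeChunk(rs, plan)
    comp <- lapply(seq_along(plan@streams), function(si)
      compressBlock(chunk@payloads[[si]], plan@streams[[si]]@codec))
    list(n = length(rs),
         ulens = vapply(chunk@payloads, length, 0L),
         comp = comp)
  }
  results <-
    if (job@workers > 1 && .Platform$OS.type == "unix") {
      res <- parallel::mclapply(bounds, compressOne,
                                mc.cores = as.integer(job@workers),
                                mc.preschedule = TRUE)
      fails <- vapply(res, inherits, TRUE, what = "try-error")
      if (any(fails)) stop(attr(res[[which(fails)[1]]], "condition"))
      res
    } else {
      lapply(bounds, compressOne)
    }

  # assemble per-stream byte sequences + chunk indexes
  streams <- vector("list", length(paths))
  for (si in seq_along(paths)) {
    payloads <- lapply(results, function(r) r$comp[[si]])
    clens <- vapply(payloads, length, 0L)
    offsets <- c(0, cumsum(clens))[seq_along(clens)]
    ulens <- vapply(results, function(r) r$ulens[[si]], 0)
    ch <- cbind(offset = offsets, clen = clens, ulen = ulens)
    if (length(clens) == 0) {
      ch <- matrix(numeric(0), ncol = 3)
      colnames(ch) <- c("offset", "clen", "ulen")
    }
    streams[[si]] <- list(path = paths[si],
                          method = plan@streams[[si]]@codec@method,
                          level = plan@streams[[si]]@codec@level,
                          bytes = do.call(c, c(list(raw(0)), payloads)),
                          totalBytes = sum(clens), chunks = ch)
  }

  # allocate + write; atomic w.r.t. the catalog
  reservedAll <- list()
  ok <- FALSE
  tryCatch({
    for (si in seq_along(streams)) {
      blocks <- allocate(handle, streams[[si]]$totalBytes)
      reservedAll[[si]] <- blocks
      streams[[si]]$blocks <- blocks
    }
    for (si in seq_along(streams))
      writeStreamBytes(handle, streams[[si]]$blocks, streams[[si]]$bytes)
    ok <- TRUE
  }, error = function(e) {
    for (blocks in reservedAll)
      tryCatch(releaseBlocks(handle, blocks), error = function(e2) NULL)
    stop(e)
  })

  keySamples <- if (!is.null(keySamplesAll))
    lapply(bounds, function(b) keySamplesAll[[b[1]]])
  desc <- new("DatasetDescriptor", name = name,
              schemaText = renderSchema(
                schemaDoc(list(), plan@schema@name, plan@schema@root)),
              headerText = parsed$header, nRecords = as.numeric(n),
              chunkRecords = job@chunkRecords,
              streams = lapply(streams, function(s)
                s[c("path", "method", "level", "blocks", "totalBytes",
                    "chunks")]),
              keySamples = keySamples)
  addDataset(handle, desc)
  invisible(desc)
}

# ---------------------------------------------------------------------------
# decompression
# ---------------------------------------------------------------------------

.chunkRecordCounts <- function(desc) {
  n <- desc@nRecords
  per <- desc@chunkRecords
  if (n == 0) return(integer(0))
  vapply(.chunkBounds(n, per), function(b) as.integer(b[2] - b[1] + 1), 0L)
}

.readChunkRecords <- function(handle, desc, plan, k) {
  counts <- .chunkRecordCounts(desc)
  payloads <- lapply(desc@streams, function(s) {
    ch <- s$chunks
    comp <- readStreamBytes(handle, desc, s$path, ch[k, "offset"],
                            ch[k, "clen"])
    out <- decompressBlock(comp, codecSpec(s$method, s$level),
                           sizeHint = max(64, ch[k, "ulen"]))
    if (length(out) != ch[k, "ulen"])
      stopData("stream '%s' chunk %d decompressed to %d bytes, expected %d",
               s$path, k, length(out), as.integer(ch[k, "ulen"]))
    out
  })
  names(payloads) <- vapply(desc@streams, function(s) s$path, "")
  deserializeChunk(new("StreamChunk", nRecords = counts[k],
                       payloads = payloads), plan)
}

#' Decompress a dataset back to text
#'
#' Emits the stored header followed by every record unparsed in original
#' order.  With a lossless configuration and no adaptors the output is
#' byte-identical to the canonical input.
#'
#' @param handle container handle.
#' @param name dataset name.
#' @param unparser `function(records) -> character` one text block per
#'   record (no trailing newline), e.g. [unparseFastqRecords()].
#' @param postAdaptors `function(record, ordinal)` transforms applied after
#'   deserialization (e.g. [refDecodeAdaptor()]).
#' @param file optional output path; written byte-exactly when given.
#' @return the output text (single string), invisibly when `file` is given.
#' @export
decompressDataset <- function(handle, name, unparser, postAdaptors = list(),
                              file = NULL) {
  desc <- getDataset(handle, name)
  schema <- resolveTypes(parseSchema(desc@schemaText))
  plan <- planStreams(schema)
  counts <- .chunkRecordCounts(desc)
  pieces <- character(length(counts) + 1L)
  pieces[1] <- desc@headerText
  done <- 0L
  for (k in seq_along(counts)) {
    rs <- .readChunkRecords(handle, desc, plan, k)
    if (length(postAdaptors))
      rs <- .applyAdaptors(rs, done + seq_along(rs), postAdaptors)
    lines <- unparser(rs)
    pieces[k + 1L] <- paste0(paste0(lines, "\n"), collapse = "")
    done <- done + length(rs)
  }
  text <- paste0(pieces, collapse = "")
  if (!is.null(file)) {
    con <- file(file, "wb")
    writeChar(text, con, eos = NULL, useBytes = TRUE)
    close(con)
    return(invisible(text))
  }
  text
}

#' Range query on a sorted dataset
#'
#' Returns exactly the records whose key lies in `[lo, hi]` (inclusive), in
#' stored order.  Only the chunks in the bisection-located interval are
#' decompressed.
#'
#' @param handle container handle.
#' @param name dataset name (must have been stored with a key function).
#' @param lo,hi inclusive key bounds.
#' @param keyFn `function(record) -> key`; the same key the dataset was
#'   sorted by (e.g. [samKeyFun()] built from the stored header).
#' @param postAdaptors record transforms applied after deserialization.
#' @param unparser optional; when given, the matching records are unparsed
#'   and the text returned instead of the record list.
#' @return list of matching records (or text when `unparser` is given),
#'   with attributes `chunksRead` and `comparisons`.
#' @export
queryRange <- function(handle, name, lo, hi, keyFn, postAdaptors = list(),
                       unparser = NULL) {
  desc <- getDataset(handle, name)
  loc <- locateChunkRange(desc, lo, hi)
  schema <- resolveTypes(parseSchema(desc@schemaText))
  plan <- planStreams(schema)
  counts <- .chunkRecordCounts(desc)
  out <- list()
  chunks <- if (loc["lastExcl"] > loc["first"])
    seq.int(loc["first"] + 1L, loc["lastExcl"]) else integer(0)
  for (k in chunks) {
    base <- if (k > 1) sum(counts[seq_len(k - 1)]) else 0L
    rs <- .readChunkRecords(handle, desc, plan, k)
    if (length(postAdaptors))
      rs <- .applyAdaptors(rs, base + seq_along(rs), postAdaptors)
    keep <- vapply(rs, function(r) {
      key <- keyFn(r)
      compareKeys(lo, key) <= 0L && compareKeys(key, hi) <= 0L
    }, TRUE)
    out <- c(out, rs[keep])
  }
  res <- if (is.null(unparser)) out else
    paste0(paste0(unparser(out), "\n"), collapse = "")
  attr(res, "chunksRead") <- length(chunks)
  attr(res, "comparisons") <- attr(loc, "comparisons")
  res
}
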