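# Chunk (de)serialization: a list of schema-conforming record values is
# turned into one byte payload per planned stream, and back.
#
# Record values mirror the schema:
#   * fixed-width integer primitive -> numeric scalar
#   * char                          -> single 1-byte string
#   * flag                          -> logical
#   * string/dna/qual               -> string (arbitrary non-NUL bytes)
#   * fixed/variable array          -> atomic vector (primitive elements)
#                                      or list (structured elements)
#   * record                        -> named list of field values
#   * union                         -> list(alt = <1-based index>,
#                                          value = <alternative's value>)
#
# Wire encodings: little-endian at the declared width, u32 lengths, u8 tags
# (0-based on the wire).  Union branches not taken contribute nothing to
# their streams.  The walk is vectorized column-wise across the chunk.

#' Serialize records into per-stream payloads
#'
#' @param records list of record values conforming to the plan's schema.
#' @param plan a [StreamPlan-class].
#' @return a [StreamChunk-class] whose payload set equals the plan's streams.
#' @export
serializeChunk <- function(records, plan) {
  stopifnot(is.list(records), is(plan, "StreamPlan"))
  acc <- new.env(parent = emptyenv())
  acc$bufs <- list()
  n <- length(records)
  if (n > 0)
    .serWalk(plan@schema@root, records, seq_len(n), "", acc)
  payloads <- lapply(streamPaths(plan), function(p) {
    b <- acc$bufs[[p]]
    if (is.null(b)) raw(0) else do.call(c, b)
  })
  names(payloads) <- streamPaths(plan)
  extra <- setdiff(names(acc$bufs), streamPaths(plan))
  if (length(extra))
    stopUsage("records produced bytes for unplanned stream '%s'", extra[1])
  new("StreamChunk", nRecords = n, payloads = payloads)
}

.emit <- function(acc, path, bytes) {
  b <- acc$bufs[[path]]
  acc$bufs[[path]] <- if (is.null(b)) list(bytes) else c(b, list(bytes))
}

# values: list (or atomic vector) of node values, one per active record
# ords:   original record ordinals, parallel to values (for diagnostics)
.serWalk <- function(type, values, ords, path, acc) {
  if (is(type, "PrimitiveType")) {
    kind <- type@kind
    if (kind %in% .STRINGLIKE_KINDS) {
      s <- as.character(unlist(values, use.names = FALSE))
      if (anyNA(s)) stopData("missing value in stream '%s'", path)
      lens <- nchar(s, type = "bytes")
      .emit(acc, paste0(path, ".len"), .packFixed(lens, 4, FALSE, path, ords))
      .emit(acc, paste0(path, ".values"),
            charToRaw(paste(s, collapse = "")))
    } else if (kind == "char") {
      s <- as.character(unlist(values, use.names = FALSE))
      bad <- which(nchar(s, type = "bytes") != 1L)
      if (length(bad))
        stopData("char field '%s' must hold exactly 1 byte (record %d)",
                 path, ords[bad[1]])
      .emit(acc, path, charToRaw(paste(s, collapse = "")))
    } else if (kind == "flag") {
      v <- as.logical(unlist(values, use.names = FALSE))
      if (anyNA(v)) stopData("missing flag value in stream '%s'", path)
      .emit(acc, path, .packFixed(as.numeric(v), 1, FALSE, path, ords))
    } else {
      v <- as.numeric(unlist(values, use.names = FALSE))
      w <- .FIXED_WIDTHS[[kind]]
      .emit(acc, path, .packFixed(v, w, kind %in% .SIGNED_KINDS, path, ords))
    }
  } else if (is(type, "FixedArrayType")) {
    k <- type@length
    lens <- if (is.list(values)) lengths(values) else
      vapply(values, length, 0L)
    bad <- which(lens != k)
    if (length(bad))
      stopData("fixed array '%s' expects %d elements, got %d (record %d)",
               path, as.integer(k), lens[bad[1]], ords[bad[1]])
    elems <- .concatValues(values)
    .serWalk(type@element, elems, rep(ords, each = k), path, acc)
  } else if (is(type, "VarArrayType")) {
    counts <- lengths(values)
    .emit(acc, paste0(path, ".len"), .packFixed(counts, 4, FALSE, path, ords))
    elems <- .concatValues(values)
    eords <- rep.int(ords, counts)
    if (.isFixedPrim(type@element)) {
      kind <- type@element@kind
      vp <- paste0(path, ".values")
      if (kind == "char") {
        s <- as.character(unlist(elems, use.names = FALSE))
        .emit(acc, vp, charToRaw(paste(s, collapse = "")))
      } else if (kind == "flag") {
        .emit(acc, vp, .packFixed(as.numeric(unlist(elems)), 1, FALSE,
                                  vp, eords))
      } else {
        .emit(acc, vp, .packFixed(as.numeric(unlist(elems)),
                                  .FIXED_WIDTHS[[kind]],
                                  kind %in% .SIGNED_KINDS, vp, eords))
      }
    } else {
      if (length(elems))
        .serWalk(type@element, elems, eords, paste0(path, ".item"), acc)
    }
  } else if (is(type, "RecordType")) {
    for (f in type@fields) {
      col <- lapply(values, function(v) {
        x <- v[[f@name]]
        if (is.null(x))
          stopData("record value missing field '%s' at '%s'", f@name, path)
        x
      })
      .serWalk(f@type, col, ords, .joinPath(path, f@name), acc)
    }
  } else if (is(type, "UnionType")) {
    nAlt <- length(type@alternatives)
    tags <- vapply(values, function(v) as.integer(v$alt), 1L)
    bad <- which(is.na(tags) | tags < 1L | tags > nAlt)
    if (length(bad))
      stopData("union tag out of range at '%s' (record %d)",
               path, ords[bad[1]])
    .emit(acc, paste0(path, ".tag"), .packFixed(tags - 1, 1, FALSE,
                                                path, ords))
    for (i in seq_len(nAlt)) {
      sel <- tags == i
      if (any(sel)) {
        vals <- lapply(values[sel], `[[`, "value")
        .serWalk(type@alternatives[[i]]@type, vals, ords[sel],
                 .joinPath(path, type@alternatives[[i]]@name), acc)
      }
    }
  } else {
    stopUsage("cannot serialize unresolved type node at '%s'", path)
  }
}

# concatenate per-record element containers into one flat container
.concatValues <- function(values) {
  if (length(values) == 0L) return(list())
  if (is.list(values) && !is.list(values[[1]]) && !is.null(values[[1]])) {
    # records hold atomic vectors -> one flat atomic vector
    return(unlist(values, use.names = FALSE, recursive = FALSE))
  }
  do.call(c, values)
}

#' Reconstruct records from per-stream payloads
#'
#' Exact inverse of [serializeChunk()].  Payloads must be internally
#' consistent: a truncated stream, a lengths stream that disagrees with its
#' values stream, trailing unconsumed bytes, or an out-of-range union tag
#' all raise data errors naming the offending stream path.
#'
#' @param chunk a [StreamChunk-class].
#' @param plan the [StreamPlan-class] the chunk was serialized under.
#' @return list of record values, of length `chunk@nRecords`.
#' @export
deserializeChunk <- function(chunk, plan) {
  stopifnot(is(chunk, "StreamChunk"), is(plan, "StreamPlan"))
  st <- new.env(parent = emptyenv())
  st$payloads <- chunk@payloads
  st$cursors <- structure(numeric(length(chunk@payloads)),
                          names = names(chunk@payloads))
  missing <- setdiff(streamPaths(plan), names(chunk@payloads))
  if (length(missing))
    stopData("chunk is missing payload for stream '%s'", missing[1])
  n <- as.integer(chunk@nRecords)
  if (n == 0L) {
    recs <- list()
  } else {
    recs <- .deWalk(plan@schema@root, n, "", st)
  }
  leftover <- vapply(names(st$payloads), function(p)
    length(st$payloads[[p]]) - st$cursors[[p]], 0)
  if (any(leftover > 0))
    stopData("stream '%s' holds %d unconsumed trailing bytes",
             names(which(leftover > 0))[1], max(leftover))
  recs
}

.readBytes <- function(st, path, nbytes) {
  p <- st$payloads[[path]]
  if (is.null(p)) stopData("chunk is missing payload for stream '%s'", path)
  cur <- st$cursors[[path]]
  if (cur + nbytes > length(p))
    stopData("truncated stream '%s': need %d bytes at offset %d, have %d",
             path, as.integer(nbytes), as.integer(cur),
             length(p) - as.integer(cur))
  st$cursors[[path]] <- cur + nbytes
  if (nbytes == 0) raw(0) else p[(cur + 1):(cur + nbytes)]
}

.splitVector <- function(x, counts, n) {
  idx <- factor(rep.int(seq_len(n), counts), levels = seq_len(n))
  unname(split(x, idx))
}

.splitList <- function(x, counts, n) {
  grp <- .splitVector(seq_along(x), counts, n)
  lapply(grp, function(g) x[g])
}

# returns a "column": an atomic vector or list of length n
.deWalk <- function(type, n, path, st) {
  if (is(type, "PrimitiveType")) {
    kind <- type@kind
    if (kind %in% .STRINGLIKE_KINDS) {
      lens <- .unpackFixed(.readBytes(st, paste0(path, ".len"), 4 * n), 4)
      s <- rawToChar(.readBytes(st, paste0(path, ".values"), sum(lens)))
      ends <- cumsum(lens)
      return(substring(s, ends - lens + 1, ends))
    }
    if (kind == "char") {
      s <- rawToChar(.readBytes(st, path, n))
      return(substring(s, seq_len(n), seq_len(n)))
    }
    if (kind == "flag")
      return(as.logical(.unpackFixed(.readBytes(st, path, n), 1)))
    w <- .FIXED_WIDTHS[[kind]]
    return(.unpackFixed(.readBytes(st, path, n * w), w,
                        kind %in% .SIGNED_KINDS))
  }
  if (is(type, "FixedArrayType")) {
    k <- as.integer(type@length)
    col <- .deWalk(type@element, n * k, path, st)
    counts <- rep.int(k, n)
    return(if (is.list(col)) .splitList(col, counts, n)
           else .splitVector(col, counts, n))
  }
  if (is(type, "VarArrayType")) {
    counts <- .unpackFixed(.readBytes(st, paste0(path, ".len"), 4 * n), 4)
    total <- as.integer(sum(counts))
    if (.isFixedPrim(type@element)) {
      kind <- type@element@kind
      vp <- paste0(path, ".values")
      col <- if (kind == "char") {
        s <- rawToChar(.readBytes(st, vp, total))
        substring(s, seq_len(total), seq_len(total))
      } else if (kind == "flag") {
        as.logical(.unpackFixed(.readBytes(st, vp, total), 1))
      } else {
        w <- .FIXED_WIDTHS[[kind]]
        .unpackFixed(.readBytes(st, vp, total * w), w,
                     kind %in% .SIGNED_KINDS)
      }
      return(.splitVector(col, counts, n))
    }
    if (is(type@element, "PrimitiveType")) {
      # variable-length byte-string elements: keep the column atomic
      col <- if (total > 0)
        .deWalk(type@element, total, paste0(path, ".item"), st)
      else character(0)
      return(.splitVector(col, counts, n))
    }
    col <- if (total > 0)
      .deWalk(type@element, total, paste0(path, ".item"), st) else list()
    if (!is.list(col)) col <- as.list(col)
    return(.splitList(col, counts, n))
  }
  if (is(type, "RecordType")) {
    nms <- vapply(type@fields, function(f) f@name, "")
    cols <- lapply(type@fields, function(f)
      .deWalk(f@type, n, .joinPath(path, f@name), st))
    return(.mapply(function(...) stats::setNames(list(...), nms),
                   cols, NULL))
  }
  if (is(type, "UnionType")) {
    nAlt <- length(type@alternatives)
    tags0 <- .unpackFixed(.readBytes(st, paste0(path, ".tag"), n), 1)
    if (any(tags0 >= nAlt))
      stopData("union tag %d out of range (%d alternatives) in stream '%s.tag'",
               as.integer(max(tags0)), nAlt, path)
    out <- vector("list", n)
    for (i in seq_len(nAlt)) {
      idx <- which(tags0 == i - 1)
      if (length(idx)) {
        vals <- .deWalk(type@alternatives[[i]]@type, length(idx),
                        .joinPath(path, type@alternatives[[i]]@name), st)
        if (!is.list(vals)) vals <- as.list(vals)
        out[idx] <- lapply(vals, function(v) list(alt = i, value = v))
      }
    }
    return(out)
  }
  stopUsage("cannot deserialize unresolved type node at '%s'", path)
}
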