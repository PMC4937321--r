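# On-disk container: three files sharing a path prefix.
#
#   <prefix>.genarc-data   block data area, pre-sized at creation to
#                          nBig*bigBlockSize + nSmall*smallBlockSize bytes.
#                          Block slots are laid out big blocks first; the
#                          last 8 bytes of every slot are a trailer
#                          (payload_len u32 LE, crc32 u32 LE), so payload
#                          capacity = slot size - 8.
#   <prefix>.genarc-meta   fixed layout: magic "GENARC01", format version
#                          u16 LE, geometry as four u64 LE (bigBlockSize,
#                          smallBlockSize, nBig, nSmall), then one state
#                          byte per block (0 free / 1 reserved / 2 occupied).
#   <prefix>.genarc-ds     dataset catalog, versioned JSON.
#
# Writers take an advisory lock file <prefix>.genarc-lock; readers of
# finalized datasets need no lock.  A dataset only becomes visible in the
# catalog after all its blocks are occupied, so reserved-but-uncataloged
# blocks are reclaimable garbage after a crash.

.META_MAGIC <- "GENARC01"
.META_VERSION <- 1

.dataPath <- function(prefix) paste0(prefix, ".genarc-data")
.metaPath <- function(prefix) paste0(prefix, ".genarc-meta")
.catPath  <- function(prefix) paste0(prefix, ".genarc-ds")
.lockPath <- function(prefix) paste0(prefix, ".genarc-lock")

.nBlocks <- function(cfg) as.integer(cfg@nBig + cfg@nSmall)

.blockSize <- function(cfg, id)
  ifelse(id < cfg@nBig, cfg@bigBlockSize, cfg@smallBlockSize)

.blockCapacity <- function(cfg, id) .blockSize(cfg, id) - 8

.blockOffset <- function(cfg, id)
  ifelse(id < cfg@nBig, id * cfg@bigBlockSize,
         cfg@nBig * cfg@bigBlockSize + (id - cfg@nBig) * cfg@smallBlockSize)

#' Create a new container
#'
#' Creates the three container files; the data file is pre-sized to the full
#' block area and all blocks start free.
#'
#' @param prefix path prefix for the three files.
#' @param config a [containerConfig()].
#' @return a [GenarcContainer-class] handle.
#' @export
createContainer <- function(prefix, config = containerConfig()) {
  stopifnot(is(config, "ContainerConfig"))
  validObject(config)
  paths <- c(.dataPath(prefix), .metaPath(prefix), .catPath(prefix))
  if (any(file.exists(paths)))
    stopUsage("container files already exist at prefix '%s'", prefix)
  size <- config@nBig * config@bigBlockSize +
    config@nSmall * config@smallBlockSize
  con <- file(.dataPath(prefix), "wb")
  if (size > 0) {
    seek(con, size - 1, rw = "write")
    writeBin(as.raw(0), con)
  }
  close(con)
  handle <- new("GenarcContainer", prefix = prefix,
                state = new.env(parent = emptyenv()))
  handle@state$config <- config
  handle@state$alloc <- integer(.nBlocks(config))
  handle@state$catalog <- list()
  handle@state$lockHeld <- FALSE
  .writeMeta(handle)
  .writeCatalog(handle)
  invisible(handle)
}

#' Open an existing container
#'
#' @param prefix path prefix used at creation.
#' @return a [GenarcContainer-class] handle.
#' @export
openContainer <- function(prefix) {
  if (!file.exists(.metaPath(prefix)))
    stopUsage("no container at prefix '%s'", prefix)
  meta <- .readMeta(.metaPath(prefix))
  handle <- new("GenarcContainer", prefix = prefix,
                state = new.env(parent = emptyenv()))
  handle@state$config <- meta$config
  handle@state$alloc <- meta$alloc
  handle@state$catalog <- .readCatalog(.catPath(prefix))
  handle@state$lockHeld <- FALSE
  invisible(handle)
}

#' Close a container handle (releases the writer lock, if held)
#'
#' @param handle a container handle.
#' @export
closeContainer <- function(handle) {
  if (isTRUE(handle@state$lockHeld)) {
    unlink(.lockPath(handle@prefix))
    handle@state$lockHeld <- FALSE
  }
  invisible(NULL)
}

.acquireLock <- function(handle) {
  if (isTRUE(handle@state$lockHeld)) return(invisible(NULL))
  lp <- .lockPath(handle@prefix)
  if (file.exists(lp))
    stopUsage("container '%s' is locked by another writer (%s)",
              handle@prefix, lp)
  writeLines(as.character(Sys.getpid()), lp)
  handle@state$lockHeld <- TRUE
  invisible(NULL)
}

.writeMeta <- function(handle) {
  cfg <- handle@state$config
  con <- file(.metaPath(handle@prefix), "wb")
  on.exit(close(con))
  writeBin(charToRaw(.META_MAGIC), con)
  writeBin(.packFixed(.META_VERSION, 2), con)
  writeBin(.packFixed(c(cfg@bigBlockSize, cfg@smallBlockSize,
                        cfg@nBig, cfg@nSmall), 8), con)
  writeBin(as.raw(handle@state$alloc), con)
  invisible(NULL)
}

.readMeta <- function(path) {
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 42 || rawToChar(r[1:8]) != .META_MAGIC)
    stopIntegrity("'%s' is not a container meta file", path)
  version <- .unpackFixed(r[9:10], 2)
  if (version != .META_VERSION)
    stopIntegrity("unsupported container format version %d", version)
  geo <- .unpackFixed(r[11:42], 8)
  config <- containerConfig(geo[1], geo[2], geo[3], geo[4])
  nb <- .nBlocks(config)
  if (length(r) != 42 + nb)
    stopIntegrity("meta file '%s' truncated (expected %d block states)",
                  path, nb)
  alloc <- as.integer(r[43:(42 + nb)])
  if (nb == 0) alloc <- integer(0)
  if (any(alloc > 2))
    stopIntegrity("invalid block state in '%s'", path)
  list(config = config, alloc = alloc)
}

# ---------------------------------------------------------------------------
# catalog (de)serialization
# ---------------------------------------------------------------------------

.descriptorToList <- function(d) {
  list(name = d@name, schema = d@schemaText, header = d@headerText,
       n_records = d@nRecords, chunk_records = d@chunkRecords,
       streams = lapply(d@streams, function(s)
         list(path = s$path, method = s$method, level = s$level,
              blocks = as.list(s$blocks), total_bytes = s$totalBytes,
              chunks = lapply(seq_len(nrow(s$chunks)), function(i)
                as.list(unname(s$chunks[i, ]))))),
       key_samples = if (is.null(d@keySamples)) NULL
                     else lapply(d@keySamples, as.list))
}

.listToDescriptor <- function(l) {
  streams <- lapply(l$streams, function(s) {
    ch <- if (length(s$chunks))
      do.call(rbind, lapply(s$chunks, function(x) as.numeric(unlist(x))))
    else matrix(numeric(0), ncol = 3)
    colnames(ch) <- c("offset", "clen", "ulen")
    list(path = s$path, method = s$method,
         level = if (is.null(s$level)) NA_real_ else as.numeric(s$level),
         blocks = as.numeric(unlist(s$blocks, use.names = FALSE)),
         totalBytes = as.numeric(s$total_bytes), chunks = ch)
  })
  ks <- if (is.null(l$key_samples)) NULL else
    lapply(l$key_samples, function(k)
      lapply(as.list(unlist(k, recursive = FALSE)), function(x)
        if (is.numeric(x)) as.numeric(x) else x))
  new("DatasetDescriptor", name = l$name, schemaText = l$schema,
      headerText = l$header, nRecords = as.numeric(l$n_records),
      chunkRecords = as.numeric(l$chunk_records), streams = streams,
      keySamples = ks)
}

.writeCatalog <- function(handle) {
  doc <- list(format = "genarc-catalog", version = 1,
              datasets = unname(lapply(handle@state$catalog,
                                       .descriptorToList)))
  jsonlite::write_json(doc, .catPath(handle@prefix), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(NULL)
}

.readCatalog <- function(path) {
  if (!file.exists(path)) return(list())
  doc <- jsonlite::read_json(path)
  cat <- lapply(doc$datasets, .listToDescriptor)
  names(cat) <- vapply(cat, function(d) d@name, "")
  cat
}

# ---------------------------------------------------------------------------
# allocation
# ---------------------------------------------------------------------------

#' Allocate blocks for a stream payload
#'
#' Greedy policy minimizing wasted big-block space: as many full big-block
#' payloads as fit, then the residual tail in the minimal number of small
#' blocks if enough are free, otherwise one more big block.  Returned blocks
#' are marked reserved; nothing is written yet.
#'
#' @param handle container handle.
#' @param nBytes payload size; 0 yields an empty allocation.
#' @return numeric vector of 0-based block ids (big blocks first).  On an
#'   out-of-space error the allocation table is unchanged.
#' @export
allocate <- function(handle, nBytes) {
  stopifnot(nBytes >= 0)
  .acquireLock(handle)
  cfg <- handle@state$config
  alloc <- handle@state$alloc
  if (nBytes == 0) return(numeric(0))
  bigCap <- cfg@bigBlockSize - 8
  smallCap <- cfg@smallBlockSize - 8
  freeBig <- which(alloc[seq_len(cfg@nBig)] == 0L) - 1
  freeSmall <- if (cfg@nSmall > 0)
    cfg@nBig + which(alloc[(cfg@nBig + 1):.nBlocks(cfg)] == 0L) - 1
  else numeric(0)

  nFullBig <- min(nBytes %/% bigCap, length(freeBig))
  rem <- nBytes - nFullBig * bigCap
  useBig <- freeBig[seq_len(nFullBig)]
  useSmall <- numeric(0)
  if (rem > 0) {
    kSmall <- ceiling(rem / smallCap)
    if (kSmall <= length(freeSmall)) {
      useSmall <- freeSmall[seq_len(kSmall)]
    } else if (rem <= bigCap && length(freeBig) > nFullBig) {
      useBig <- freeBig[seq_len(nFullBig + 1)]
    } else {
      stopData("out of space: cannot allocate %s bytes (%d big, %d small blocks free)",
               format(nBytes), length(freeBig) - nFullBig, length(freeSmall))
    }
  }
  ids <- c(useBig, useSmall)
  alloc[ids + 1] <- 1L
  handle@state$alloc <- alloc
  .writeMeta(handle)
  ids
}

#' Return reserved blocks to the free pool (write abandoned)
#'
#' @param handle container handle.
#' @param blocks block ids previously returned by [allocate()].
#' @export
releaseBlocks <- function(handle, blocks) {
  if (length(blocks) == 0) return(invisible(NULL))
  .acquireLock(handle)
  alloc <- handle@state$alloc
  if (any(alloc[blocks + 1] != 1L))
    stopUsage("can only release reserved blocks")
  alloc[blocks + 1] <- 0L
  handle@state$alloc <- alloc
  .writeMeta(handle)
  invisible(NULL)
}

# per-block payload lengths when `total` bytes fill `blocks` in order
.payloadLens <- function(cfg, blocks, total) {
  caps <- .blockCapacity(cfg, blocks)
  fills <- pmin(caps, pmax(0, total - c(0, cumsum(caps))[seq_along(caps)]))
  fills
}

#' Write a stream payload into reserved blocks
#'
#' Fills the blocks in order, each to capacity except the last, and stamps
#' every block's trailer (payload length + CRC32).  On success the blocks
#' become occupied.
#'
#' @param handle container handle.
#' @param blocks reserved block ids from [allocate()].
#' @param data raw payload; must fit the blocks' total capacity.
#' @export
writeStreamBytes <- function(handle, blocks, data) {
  stopifnot(is.raw(data))
  .acquireLock(handle)
  cfg <- handle@state$config
  alloc <- handle@state$alloc
  if (length(blocks) == 0) {
    if (length(data) > 0)
      stopData("capacity overflow: %d bytes into 0 blocks", length(data))
    return(invisible(NULL))
  }
  notRes <- blocks[alloc[blocks + 1] != 1L]
  if (length(notRes))
    stopUsage("block %d is not reserved", as.integer(notRes[1]))
  caps <- .blockCapacity(cfg, blocks)
  if (length(data) > sum(caps))
    stopData("capacity overflow: %d bytes into %d bytes of block capacity",
             length(data), as.integer(sum(caps)))
  fills <- .payloadLens(cfg, blocks, length(data))
  con <- file(.dataPath(handle@prefix), "r+b")
  on.exit(close(con))
  done <- 0
  for (i in seq_along(blocks)) {
    id <- blocks[i]
    chunkBytes <- data[seq_len(fills[i]) + done]
    done <- done + fills[i]
    off <- .blockOffset(cfg, id)
    seek(con, off, rw = "write")
    if (fills[i] > 0) writeBin(chunkBytes, con)
    seek(con, off + .blockSize(cfg, id) - 8, rw = "write")
    writeBin(c(.packFixed(fills[i], 4), .packFixed(.crc32(chunkBytes), 4)),
             con)
  }
  alloc[blocks + 1] <- 2L
  handle@state$alloc <- alloc
  .writeMeta(handle)
  invisible(NULL)
}

# read one occupied block's payload, verifying its trailer
.readBlockPayload <- function(con, cfg, id, expectLen) {
  off <- .blockOffset(cfg, id)
  seek(con, off + .blockSize(cfg, id) - 8, rw = "read")
  trailer <- readBin(con, raw(), 8)
  storedLen <- .unpackFixed(trailer[1:4], 4)
  storedCrc <- .unpackFixed(trailer[5:8], 4)
  if (storedLen != expectLen)
    stopIntegrity("checksum mismatch in block %d: stored payload length %d, expected %d",
                  as.integer(id), as.integer(storedLen),
                  as.integer(expectLen))
  seek(con, off, rw = "read")
  payload <- readBin(con, raw(), storedLen)
  if (.crc32(payload) != storedCrc)
    stopIntegrity("checksum mismatch in block %d", as.integer(id))
  payload
}

#' Read a byte range of a stored stream
#'
#' Maps logical stream offsets through the descriptor's block list and
#' verifies the CRC32 of every touched block before returning.
#'
#' @param handle container handle.
#' @param descriptor a [DatasetDescriptor-class].
#' @param path stream path within the dataset.
#' @param offset 0-based logical offset into the stream payload.
#' @param length number of bytes.
#' @return raw vector of `length` bytes.
#' @export
readStreamBytes <- function(handle, descriptor, path, offset, length) {
  cfg <- handle@state$config
  s <- NULL
  for (cand in descriptor@streams) if (cand$path == path) { s <- cand; break }
  if (is.null(s))
    stopUsage("dataset '%s' has no stream '%s'", descriptor@name, path)
  if (offset < 0 || length < 0 || offset + length > s$totalBytes)
    stopUsage("range [%s, %s) out of bounds for stream '%s' (%s bytes)",
              format(offset), format(offset + length), path,
              format(s$totalBytes))
  if (length == 0) return(raw(0))
  fills <- .payloadLens(cfg, s$blocks, s$totalBytes)
  ends <- cumsum(fills)
  starts <- ends - fills
  touched <- which(starts < offset + length & ends > offset)
  con <- file(.dataPath(handle@prefix), "rb")
  on.exit(close(con))
  parts <- lapply(touched, function(i) {
    payload <- .readBlockPayload(con, cfg, s$blocks[i], fills[i])
    lo <- max(offset, starts[i]) - starts[i]
    hi <- min(offset + length, ends[i]) - starts[i]
    payload[(lo + 1):hi]
  })
  do.call(c, parts)
}

# ---------------------------------------------------------------------------
# catalog operations
# ---------------------------------------------------------------------------

#' Dataset catalog operations
#'
#' `addDataset` registers a finalized dataset (its blocks must already be
#' occupied); names are unique within a container.  `listDatasets` returns
#' the stored names, `getDataset` one descriptor.
#'
#' @param handle container handle.
#' @param descriptor a [DatasetDescriptor-class].
#' @export
addDataset <- function(handle, descriptor) {
  stopifnot(is(descriptor, "DatasetDescriptor"))
  validObject(descriptor)
  .acquireLock(handle)
  if (descriptor@name %in% names(handle@state$catalog))
    stopUsage("dataset '%s' already exists in container", descriptor@name)
  handle@state$catalog[[descriptor@name]] <- descriptor
  .writeCatalog(handle)
  invisible(descriptor)
}

#' @rdname addDataset
#' @export
listDatasets <- function(handle) names(handle@state$catalog)

#' @rdname addDataset
#' @param name dataset name.
#' @export
getDataset <- function(handle, name) {
  d <- handle@state$catalog[[name]]
  if (is.null(d)) stopUsage("no dataset '%s' in container", name)
  d
}

# ---------------------------------------------------------------------------
# verify & shrink
# ---------------------------------------------------------------------------

#' Verify every occupied block's checksum
#'
#' Recomputes the CRC32 of each occupied block and reports corrupt blocks
#' together with the dataset/stream referencing them.  Free and reserved
#' blocks are not checked.
#'
#' @param handle container handle.
#' @return data.frame with columns `blockId`, `dataset`, `stream` (0 rows if
#'   the container is pristine).
#' @export
verifyContainer <- function(handle) {
  cfg <- handle@state$config
  alloc <- handle@state$alloc
  occ <- which(alloc == 2L) - 1
  refmap <- new.env(parent = emptyenv())
  for (d in handle@state$catalog)
    for (s in d@streams) {
      fills <- .payloadLens(cfg, s$blocks, s$totalBytes)
      for (i in seq_along(s$blocks))
        assign(as.character(s$blocks[i]),
               list(dataset = d@name, stream = s$path, len = fills[i]),
               envir = refmap)
    }
  bad <- list()
  if (length(occ)) {
    con <- file(.dataPath(handle@prefix), "rb")
    on.exit(close(con))
    for (id in occ) {
      ref <- refmap[[as.character(id)]]
      ok <- tryCatch({
        if (is.null(ref)) {
          # occupied but unreferenced: verify against its own stored length
          off <- .blockOffset(cfg, id)
          seek(con, off + .blockSize(cfg, id) - 8, rw = "read")
          trailer <- readBin(con, raw(), 8)
          storedLen <- .unpackFixed(trailer[1:4], 4)
          if (storedLen > .blockCapacity(cfg, id)) FALSE
          else {
            seek(con, off, rw = "read")
            .crc32(readBin(con, raw(), storedLen)) ==
              .unpackFixed(trailer[5:8], 4)
          }
        } else {
          .readBlockPayload(con, cfg, id, ref$len)
          TRUE
        }
      }, genarcIntegrityError = function(e) FALSE)
      if (!isTRUE(ok))
        bad[[length(bad) + 1L]] <-
          data.frame(blockId = id,
                     dataset = if (is.null(ref)) NA_character_ else ref$dataset,
                     stream = if (is.null(ref)) NA_character_ else ref$stream)
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(blockId = numeric(0), dataset = character(0),
                  stream = character(0))
}

#' Shrink a container to its occupied blocks
#'
#' Writes a new container holding only the occupied blocks (ids remapped in
#' every descriptor); every dataset decodes byte-identically afterwards and
#' the new data file has exactly occupied-blocks size.
#'
#' @param handle container handle (must hold no reserved blocks).
#' @param outPrefix path prefix for the shrunk container.
#' @return the new [ContainerConfig-class], invisibly; reopen the shrunk
#'   container with [openContainer()].
#' @export
shrinkContainer <- function(handle, outPrefix) {
  cfg <- handle@state$config
  alloc <- handle@state$alloc
  if (any(alloc == 1L))
    stopUsage("cannot shrink: %d blocks are reserved (unfinalized write)",
              sum(alloc == 1L))
  occ <- which(alloc == 2L) - 1
  occBig <- occ[occ < cfg@nBig]
  occSmall <- occ[occ >= cfg@nBig]
  newCfg <- containerConfig(cfg@bigBlockSize, cfg@smallBlockSize,
                            length(occBig), length(occSmall))
  out <- createContainer(outPrefix, newCfg)
  # old id -> new id (relative order preserved within each size class)
  remap <- new.env(parent = emptyenv())
  for (i in seq_along(occBig))
    assign(as.character(occBig[i]), i - 1, envir = remap)
  for (i in seq_along(occSmall))
    assign(as.character(occSmall[i]), length(occBig) + i - 1, envir = remap)
  if (length(occ)) {
    src <- file(.dataPath(handle@prefix), "rb")
    dst <- file(.dataPath(outPrefix), "r+b")
    for (id in occ) {
      nid <- remap[[as.character(id)]]
      seek(src, .blockOffset(cfg, id), rw = "read")
      slot <- readBin(src, raw(), .blockSize(cfg, id))
      seek(dst, .blockOffset(newCfg, nid), rw = "write")
      writeBin(slot, dst)
    }
    close(src); close(dst)
  }
  out@state$alloc <- rep(2L, .nBlocks(newCfg))
  out@state$catalog <- lapply(handle@state$catalog, function(d) {
    d@streams <- lapply(d@streams, function(s) {
      s$blocks <- vapply(s$blocks, function(b)
        remap[[as.character(b)]], 0)
      s
    })
    d
  })
  .writeMeta(out)
  .writeCatalog(out)
  closeContainer(out)
  invisible(newCfg)
}
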