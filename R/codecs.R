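# Registry of block compression methods.  Each stream chunk is compressed
# independently through one of these; compressed blocks carry no
# self-describing header (the CodecSpec lives in the dataset catalog).

.codecRegistry <- new.env(parent = emptyenv())

#' Register a block compression method
#'
#' Built-ins are `raw` (identity), `gzip` (zlib, levels 1-9), `bzip2`
#' (levels 1-9) and `lzma` (xz, presets 0-9).  Additional methods — e.g. a
#' PPMd implementation — can be plugged in at run time: both functions must
#' be pure byte-to-byte transforms with
#' `decompress(compress(x)) == x` for every raw vector `x`, and `compress`
#' must be deterministic for a fixed `(data, level)`.
#'
#' @param name method name; must not already be registered.
#' @param compress `function(data, level)` raw -> raw.
#' @param decompress `function(data, sizeHint)` raw -> raw.
#' @param levelRange integer range `c(min, max)` of accepted levels.
#' @param defaultLevel level used when a [codecSpec()] carries `NA`.
#' @return invisibly, the method name.
#' @export
registerCodec <- function(name, compress, decompress, levelRange,
                          defaultLevel = levelRange[2]) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopUsage("codec name must be a non-empty string")
  if (exists(name, envir = .codecRegistry, inherits = FALSE))
    stopUsage("codec '%s' is already registered", name)
  stopifnot(is.function(compress), is.function(decompress),
            length(levelRange) == 2L, levelRange[1] <= levelRange[2],
            defaultLevel >= levelRange[1], defaultLevel <= levelRange[2])
  assign(name, list(compress = compress, decompress = decompress,
                    levelRange = as.numeric(levelRange),
                    defaultLevel = as.numeric(defaultLevel)),
         envir = .codecRegistry)
  invisible(name)
}

#' @describeIn registerCodec is a method registered?
#' @export
codecRegistered <- function(name)
  exists(name, envir = .codecRegistry, inherits = FALSE)

#' @describeIn registerCodec names of all registered methods.
#' @export
codecNames <- function() sort(ls(.codecRegistry))

#' @describeIn registerCodec accepted level range of a method.
#' @export
codecLevelRange <- function(name) .codecLookup(name)$levelRange

#' @describeIn registerCodec remove a registered method (plug-in management;
#'   built-ins come back on package reload).
#' @export
unregisterCodec <- function(name) {
  if (codecRegistered(name)) rm(list = name, envir = .codecRegistry)
  invisible(name)
}

.codecLookup <- function(name) {
  if (!codecRegistered(name))
    stopData("codec unavailable: '%s' is not registered", name)
  get(name, envir = .codecRegistry, inherits = FALSE)
}

.codecLevel <- function(spec, entry) {
  lv <- spec@level
  if (is.na(lv)) return(entry$defaultLevel)
  if (lv < entry$levelRange[1] || lv > entry$levelRange[2])
    stopUsage("level %s out of range [%d, %d] for codec '%s'",
              format(lv), as.integer(entry$levelRange[1]),
              as.integer(entry$levelRange[2]), spec@method)
  lv
}

#' Compress / decompress one block
#'
#' Deterministic for fixed `(data, spec)`.  Corrupt compressed input raises
#' a `genarcCodecError` (a data error), distinct from the container layer's
#' checksum (`genarcIntegrityError`) failures.
#'
#' @param data raw vector.
#' @param spec a [codecSpec()].
#' @param sizeHint expected decompressed size (an optimization only; any
#'   value yields correct output).
#' @return raw vector.
#' @export
compressBlock <- function(data, spec) {
  stopifnot(is.raw(data), is(spec, "CodecSpec"))
  entry <- .codecLookup(spec@method)
  entry$compress(data, .codecLevel(spec, entry))
}

#' @rdname compressBlock
#' @export
decompressBlock <- function(data, spec, sizeHint = 4 * length(data) + 64) {
  stopifnot(is.raw(data), is(spec, "CodecSpec"))
  entry <- .codecLookup(spec@method)
  .codecLevel(spec, entry)  # validate level even on the decode path
  tryCatch(entry$decompress(data, sizeHint),
           error = function(e) {
             if (inherits(e, "genarcError")) stop(e)
             .genarcStop(c("genarcCodecError", "genarcDataError"),
                         "codec '%s' failed to decompress block: %s",
                         spec@method, conditionMessage(e))
           })
}

.registerBuiltinCodecs <- function() {
  for (nm in c("raw", "gzip", "bzip2", "lzma")) unregisterCodec(nm)
  registerCodec("raw",
                function(data, level) data,
                function(data, sizeHint) data,
                levelRange = c(0, 0), defaultLevel = 0)
  registerCodec("gzip",
                function(data, level) .Call(C_gzip_compress, data,
                                            as.integer(level)),
                function(data, sizeHint) .Call(C_gzip_decompress, data,
                                               as.numeric(sizeHint)),
                levelRange = c(1, 9), defaultLevel = 6)
  registerCodec("bzip2",
                function(data, level) .Call(C_bzip2_compress, data,
                                            as.integer(level)),
                function(data, sizeHint) .Call(C_bzip2_decompress, data,
                                               as.numeric(sizeHint)),
                levelRange = c(1, 9), defaultLevel = 9)
  registerCodec("lzma",
                function(data, level) .Call(C_lzma_compress, data,
                                            as.integer(level)),
                function(data, sizeHint) .Call(C_lzma_decompress, data,
                                               as.numeric(sizeHint)),
                levelRange = c(0, 9), defaultLevel = 6)
  invisible(NULL)
}

# default codec for fields with no annotation anywhere up the field chain
.defaultCodec <- function() codecSpec("gzip", 6)
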