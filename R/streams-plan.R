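# Flattening of a resolved record schema into column streams.
#
# Rules (deterministic; equal schemas give equal plans):
#   * fixed-width primitive field f        -> stream "f"        (values)
#   * string/dna/qual field f              -> "f.len" (lengths, u32)
#                                             + "f.values" (byte payload)
#   * fixed array                          -> element streams at the same
#                                             path (count is known statically)
#   * variable array of fixed-width prims  -> "f.len" + "f.values"
#   * variable array of anything else     -> "f.len" + element streams
#                                             under "f.item"
#   * nested record                        -> recurse with dotted prefix
#   * union u                              -> "u.tag" (u8) + per-alternative
#                                             streams under "u.<alt>"
#
# Every stream inherits the nearest enclosing field's codec annotation;
# unannotated chains fall back to gzip level 6.

#' Derive the column-stream plan of a record schema
#'
#' @param schema a [RecordSchema-class] from [resolveTypes()].
#' @return a [StreamPlan-class].
#' @examples
#' sch <- resolveTypes(parseSchema(
#'   "@record Fastq { name: string @gzip; seq: dna @bzip2; qual: qual @bzip2; }"))
#' planStreams(sch)   # 6 streams: {name,seq,qual} x {len,values}
#' @export
planStreams <- function(schema) {
  stopifnot(is(schema, "RecordSchema"))
  acc <- new.env(parent = emptyenv())
  acc$streams <- list()
  .planWalk(schema@root, "", NULL, acc)
  new("StreamPlan", schema = schema, streams = acc$streams)
}

.joinPath <- function(path, name)
  if (nzchar(path)) paste0(path, ".", name) else name

.addStream <- function(acc, path, role, width, kind, codec) {
  if (is.null(codec)) codec <- .defaultCodec()
  acc$streams[[length(acc$streams) + 1L]] <-
    new("StreamSpec", path = path, role = role,
        elementWidth = as.numeric(width), kind = kind, codec = codec)
}

.isFixedPrim <- function(t)
  is(t, "PrimitiveType") && t@kind %in% names(.FIXED_WIDTHS)

.planWalk <- function(type, path, codec, acc) {
  if (is(type, "PrimitiveType")) {
    if (type@kind %in% names(.FIXED_WIDTHS)) {
      .addStream(acc, path, "values", .FIXED_WIDTHS[[type@kind]],
                 type@kind, codec)
    } else {
      .addStream(acc, paste0(path, ".len"), "lengths", 4, "len", codec)
      .addStream(acc, paste0(path, ".values"), "values", 0, "bytes", codec)
    }
  } else if (is(type, "FixedArrayType")) {
    .planWalk(type@element, path, codec, acc)
  } else if (is(type, "VarArrayType")) {
    .addStream(acc, paste0(path, ".len"), "lengths", 4, "len", codec)
    if (.isFixedPrim(type@element)) {
      .addStream(acc, paste0(path, ".values"), "values",
                 .FIXED_WIDTHS[[type@element@kind]], type@element@kind, codec)
    } else {
      .planWalk(type@element, paste0(path, ".item"), codec, acc)
    }
  } else if (is(type, "RecordType")) {
    for (f in type@fields) {
      eff <- if (is.null(f@codec)) codec else f@codec
      .planWalk(f@type, .joinPath(path, f@name), eff, acc)
    }
  } else if (is(type, "UnionType")) {
    .addStream(acc, paste0(path, ".tag"), "tag", 1, "tag", codec)
    for (a in type@alternatives) {
      eff <- if (is.null(a@codec)) codec else a@codec
      .planWalk(a@type, .joinPath(path, a@name), eff, acc)
    }
  } else {
    stopUsage("cannot plan unresolved type node at '%s'", path)
  }
}
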