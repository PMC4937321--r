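#' @import methods
NULL

# ---------------------------------------------------------------------------
# Error conditions
#
# Three user-visible condition classes map onto the toolchain exit codes:
# usage (1), data (2), integrity (3).  All inherit from genarcError.
# ---------------------------------------------------------------------------

.genarcStop <- function(class, fmt, ..., fields = list()) {
  cond <- structure(
    class = c(class, "genarcError", "error", "condition"),
    c(list(message = sprintf(fmt, ...), call = sys.call(-2)), fields)
  )
  stop(cond)
}

stopUsage <- function(fmt, ..., fields = list())
  .genarcStop("genarcUsageError", fmt, ..., fields = fields)

stopData <- function(fmt, ..., fields = list())
  .genarcStop("genarcDataError", fmt, ..., fields = fields)

stopIntegrity <- function(fmt, ..., fields = list())
  .genarcStop("genarcIntegrityError", fmt, ..., fields = fields)

# Schema diagnostics carry line/column so editors can jump to the offence.
stopSchema <- function(line, col, fmt, ...) {
  .genarcStop(c("genarcSchemaError", "genarcDataError"),
              "schema error at line %d, column %d: %s", line, col,
              sprintf(fmt, ...),
              fields = list(line = line, col = col))
}

# ---------------------------------------------------------------------------
# Codec specification
# ---------------------------------------------------------------------------

#' Codec specification
#'
#' A compression method name plus an integer preset level.  `NA` level means
#' "use the method's default level", resolved by [resolveTypes()].
#'
#' @slot method character(1), a registered codec name (e.g. `"gzip"`).
#' @slot level numeric(1) preset level, or `NA`.
#' @export
setClass("CodecSpec",
         representation(method = "character", level = "numeric"))

#' @param method codec name.
#' @param level preset level or `NA` for the method default.
#' @rdname CodecSpec-class
#' @export
codecSpec <- function(method, level = NA_real_) {
  if (!is.character(method) || length(method) != 1L || !nzchar(method))
    stopUsage("codec method must be a non-empty string")
  new("CodecSpec", method = method, level = as.numeric(level)[1])
}

setMethod("show", "CodecSpec", function(object) {
  cat(sprintf("<codec %s%s>\n", object@method,
              if (is.na(object@level)) "" else sprintf("(%d)", as.integer(object@level))))
})

# ---------------------------------------------------------------------------
# Schema type tree
#
# A record type is a tree of TypeNode objects.  Every node carries the source
# line/column it was parsed from (NA for programmatically built nodes);
# structural equality ignores positions.
# ---------------------------------------------------------------------------

#' Virtual parent of all schema type nodes
#'
#' @slot srcLine,srcCol source position the node was parsed from (`NA` for
#'   programmatically constructed nodes).
#' @export
setClass("TypeNode",
         representation("VIRTUAL", srcLine = "numeric", srcCol = "numeric"),
         prototype(srcLine = NA_real_, srcCol = NA_real_))

.PRIMITIVE_KINDS <- c("u8", "u16", "u32", "u64", "i32", "i64",
                      "char", "flag", "string", "dna", "qual")
.FIXED_WIDTHS <- c(u8 = 1, u16 = 2, u32 = 4, u64 = 8, i32 = 4, i64 = 8,
                   char = 1, flag = 1)
.SIGNED_KINDS <- c("i32", "i64")
.STRINGLIKE_KINDS <- c("string", "dna", "qual")

#' Primitive type node
#'
#' Fixed-width integers (`u8`..`u64`, `i32`, `i64`), single bytes (`char`),
#' booleans (`flag`) and the variable-length byte-string types.  `dna` and
#' `qual` are semantically distinct from `string` (they drive type-aware
#' adaptors and codec choices) but share its wire encoding.
#'
#' @slot kind one of the primitive kind names.
#' @export
setClass("PrimitiveType", contains = "TypeNode",
         representation(kind = "character"),
         validity = function(object) {
           if (!object@kind %in% .PRIMITIVE_KINDS)
             return(sprintf("unknown primitive kind '%s'", object@kind))
           TRUE
         })

#' @param kind primitive kind name.
#' @rdname PrimitiveType-class
#' @export
primitiveType <- function(kind) new("PrimitiveType", kind = kind)

setClassUnion("CodecSpecOrNULL", c("CodecSpec", "NULL"))

#' Field of a record (or alternative of a union)
#'
#' @slot name identifier.
#' @slot type the field's [TypeNode-class].
#' @slot codec optional [CodecSpec-class] annotation (`NULL` = inherit).
#' @export
setClass("FieldDef",
         representation(name = "character", type = "TypeNode",
                        codec = "CodecSpecOrNULL",
                        srcLine = "numeric", srcCol = "numeric"),
         prototype(codec = NULL, srcLine = NA_real_, srcCol = NA_real_),
         validity = function(object) {
           if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", object@name))
             return(sprintf("invalid field name '%s'", object@name))
           TRUE
         })

#' @param name field name; @param type field type; @param codec optional codec.
#' @rdname FieldDef-class
#' @export
fieldDef <- function(name, type, codec = NULL)
  new("FieldDef", name = name, type = type, codec = codec)

#' Fixed-length array type
#' @slot element element type. @slot length fixed element count (>= 1).
#' @export
setClass("FixedArrayType", contains = "TypeNode",
         representation(element = "TypeNode", length = "numeric"),
         validity = function(object) {
           if (length(object@length) != 1L || is.na(object@length) ||
               object@length < 1 || object@length != trunc(object@length))
             return("fixed array length must be a positive integer")
           TRUE
         })

#' @param element element type. @param length element count.
#' @rdname FixedArrayType-class
#' @export
fixedArrayType <- function(element, length)
  new("FixedArrayType", element = element, length = as.numeric(length))

#' Variable-length array type
#' @slot element element type.
#' @export
setClass("VarArrayType", contains = "TypeNode",
         representation(element = "TypeNode"))

#' @param element element type.
#' @rdname VarArrayType-class
#' @export
varArrayType <- function(element) new("VarArrayType", element = element)

#' Record (struct) type
#' @slot fields ordered list of [FieldDef-class] with unique names.
#' @export
setClass("RecordType", contains = "TypeNode",
         representation(fields = "list"),
         validity = function(object) {
           nms <- vapply(object@fields, function(f) f@name, "")
           if (anyDuplicated(nms))
             return(sprintf("duplicate field name '%s'", nms[duplicated(nms)][1]))
           TRUE
         })

#' @param fields list of [FieldDef-class].
#' @rdname RecordType-class
#' @export
recordType <- function(fields) new("RecordType", fields = fields)

#' Tagged union type
#' @slot alternatives ordered list of [FieldDef-class] (>= 2, unique names).
#' @export
setClass("UnionType", contains = "TypeNode",
         representation(alternatives = "list"),
         validity = function(object) {
           if (length(object@alternatives) < 2L)
             return("union must have at least 2 alternatives")
           nms <- vapply(object@alternatives, function(f) f@name, "")
           if (anyDuplicated(nms))
             return(sprintf("duplicate union alternative '%s'",
                            nms[duplicated(nms)][1]))
           TRUE
         })

#' @param alternatives list of [FieldDef-class].
#' @rdname UnionType-class
#' @export
unionType <- function(alternatives) new("UnionType", alternatives = alternatives)

#' Reference to a previously defined named type
#' @slot name the referenced definition's name.
#' @export
setClass("NamedRefType", contains = "TypeNode",
         representation(name = "character"))

#' @param name referenced type name.
#' @rdname NamedRefType-class
#' @export
namedRefType <- function(name) new("NamedRefType", name = name)

#' Parsed schema document
#'
#' An ordered set of named type definitions plus exactly one entry record
#' (the type marked with the `@record` directive).  Produced by
#' [parseSchema()]; not yet resolved (may still contain named references).
#'
#' @slot defs named list of [TypeNode-class] definitions, in source order.
#' @slot entryName name of the entry record.
#' @slot entry the entry [RecordType-class].
#' @export
setClass("SchemaDoc",
         representation(defs = "list", entryName = "character",
                        entry = "RecordType"))

#' @param defs named list of type definitions.
#' @param entryName entry record name.
#' @param entry entry record type.
#' @rdname SchemaDoc-class
#' @export
schemaDoc <- function(defs = list(), entryName, entry)
  new("SchemaDoc", defs = defs, entryName = entryName, entry = entry)

setMethod("show", "SchemaDoc", function(object) {
  cat(renderSchema(object))
})

#' Resolved record schema
#'
#' The entry record with every named reference inlined and codec levels
#' defaulted; the input to [planStreams()].
#'
#' @slot name entry record name.
#' @slot root the fully resolved [RecordType-class].
#' @export
setClass("RecordSchema",
         representation(name = "character", root = "RecordType"))

setMethod("show", "RecordSchema", function(object) {
  cat(sprintf("Resolved record schema '%s':\n", object@name))
  cat(renderSchema(schemaDoc(list(), object@name, object@root)))
})

# ---------------------------------------------------------------------------
# Stream plan
# ---------------------------------------------------------------------------

#' One column stream of a plan
#'
#' @slot path dotted field path (e.g. `"seq.values"`).
#' @slot role `"values"`, `"lengths"` or `"tag"`.
#' @slot elementWidth bytes per element for fixed-width streams, 0 for
#'   variable byte payloads.
#' @slot kind wire kind (primitive kind, `"len"`, `"tag"` or `"bytes"`).
#' @slot codec effective [CodecSpec-class] for the stream.
#' @export
setClass("StreamSpec",
         representation(path = "character", role = "character",
                        elementWidth = "numeric", kind = "character",
                        codec = "CodecSpec"),
         validity = function(object) {
           if (!object@role %in% c("values", "lengths", "tag"))
             return(sprintf("unknown stream role '%s'", object@role))
           TRUE
         })

#' Column-stream decomposition of a record schema
#'
#' @slot schema the [RecordSchema-class] the plan was derived from.
#' @slot streams list of [StreamSpec-class], in deterministic schema order.
#' @export
setClass("StreamPlan",
         representation(schema = "RecordSchema", streams = "list"),
         validity = function(object) {
           p <- vapply(object@streams, function(s) s@path, "")
           if (anyDuplicated(p))
             return(sprintf("duplicate stream path '%s'", p[duplicated(p)][1]))
           TRUE
         })

#' @describeIn StreamPlan-class stream paths in plan order.
#' @param plan a [StreamPlan-class].
#' @export
streamPaths <- function(plan) vapply(plan@streams, function(s) s@path, "")

setMethod("show", "StreamPlan", function(object) {
  cat(sprintf("Stream plan for record '%s' (%d streams):\n",
              object@schema@name, length(object@streams)))
  for (s in object@streams)
    cat(sprintf("  %-28s %-8s width=%d  %s(%s)\n", s@path, s@role,
                as.integer(s@elementWidth), s@codec@method,
                if (is.na(s@codec@level)) "default"
                else as.integer(s@codec@level)))
})

#' A chunk of records serialized into per-stream byte payloads
#'
#' @slot nRecords number of records in the chunk.
#' @slot payloads named list (stream path -> raw vector).
#' @export
setClass("StreamChunk",
         representation(nRecords = "numeric", payloads = "list"))

setMethod("show", "StreamChunk", function(object) {
  cat(sprintf("<stream chunk: %d records, %d streams, %d bytes>\n",
              as.integer(object@nRecords), length(object@payloads),
              sum(vapply(object@payloads, length, 0L))))
})

# ---------------------------------------------------------------------------
# Container
# ---------------------------------------------------------------------------

#' Container geometry
#'
#' Block sizes and counts are fixed once when the container is created.
#' Each block reserves its final 8 bytes for a trailer (payload length +
#' CRC32), so the usable payload capacity is `size - 8`.
#'
#' @slot bigBlockSize,smallBlockSize block sizes in bytes (both >= 64,
#'   small < big).
#' @slot nBig,nSmall block counts (>= 0).
#' @export
setClass("ContainerConfig",
         representation(bigBlockSize = "numeric", smallBlockSize = "numeric",
                        nBig = "numeric", nSmall = "numeric"),
         validity = function(object) {
           with_slots <- c(object@bigBlockSize, object@smallBlockSize,
                           object@nBig, object@nSmall)
           if (any(is.na(with_slots)) || any(with_slots != trunc(with_slots)))
             return("container geometry must be whole numbers")
           if (object@smallBlockSize >= object@bigBlockSize)
             return("small block size must be smaller than big block size")
           if (object@bigBlockSize < 64 || object@smallBlockSize < 64)
             return("block sizes must be at least 64 bytes")
           if (object@nBig < 0 || object@nSmall < 0)
             return("block counts must be non-negative")
           TRUE
         })

#' @param bigBlockSize,smallBlockSize block sizes in bytes.
#' @param nBig,nSmall block counts.
#' @rdname ContainerConfig-class
#' @export
containerConfig <- function(bigBlockSize = 8 * 1024^2,
                            smallBlockSize = 64 * 1024,
                            nBig = 16, nSmall = 64) {
  new("ContainerConfig", bigBlockSize = as.numeric(bigBlockSize),
      smallBlockSize = as.numeric(smallBlockSize),
      nBig = as.numeric(nBig), nSmall = as.numeric(nSmall))
}

setMethod("show", "ContainerConfig", function(object) {
  cat(sprintf("<container config: %d big x %d B, %d small x %d B>\n",
              as.integer(object@nBig), as.integer(object@bigBlockSize),
              as.integer(object@nSmall), as.integer(object@smallBlockSize)))
})

setClassUnion("listOrNULL", c("list", "NULL"))

#' Descriptor of one stored dataset
#'
#' Everything needed to decode a dataset: its canonical schema text, the
#' input file's free-text header, per-stream codec + block list + per-chunk
#' index, and (for datasets stored sorted) the first key of every chunk.
#'
#' @slot name dataset name (unique within a container).
#' @slot schemaText canonical schema rendering.
#' @slot headerText input header, verbatim (may be `""`).
#' @slot nRecords total record count.
#' @slot chunkRecords records per chunk used at compression time.
#' @slot streams list, one entry per stream: `list(path, method, level,
#'   blocks, totalBytes, chunks)` where `chunks` is a numeric matrix with
#'   columns `offset`, `clen`, `ulen` (compressed offset/length and
#'   uncompressed length of each chunk within the stream).
#' @slot keySamples `NULL`, or a list with the first key of each chunk.
#' @export
setClass("DatasetDescriptor",
         representation(name = "character", schemaText = "character",
                        headerText = "character", nRecords = "numeric",
                        chunkRecords = "numeric", streams = "list",
                        keySamples = "listOrNULL"),
         prototype(keySamples = NULL),
         validity = function(object) {
           for (s in object@streams) {
             ch <- s$chunks
             if (nrow(ch) > 0) {
               if (any(diff(ch[, "offset"]) <= 0) && nrow(ch) > 1)
                 return(sprintf("stream '%s': chunk offsets not increasing", s$path))
               if (any(ch[, "offset"] + ch[, "clen"] >
                       c(ch[-1, "offset"], s$totalBytes) + 1e-9))
                 return(sprintf("stream '%s': overlapping chunks", s$path))
             }
             if (abs(sum(ch[, "clen"]) - s$totalBytes) > 1e-9)
               return(sprintf("stream '%s': chunk lengths do not sum to total",
                              s$path))
           }
           if (!is.null(object@keySamples)) {
             ks <- object@keySamples
             nch <- if (length(object@streams)) nrow(object@streams[[1]]$chunks) else 0L
             if (length(ks) != nch)
               return("one key sample per chunk required")
             if (length(ks) > 1)
               for (i in 2:length(ks))
                 if (compareKeys(ks[[i - 1]], ks[[i]]) > 0)
                   return("key samples must be nondecreasing")
           }
           TRUE
         })

#' @describeIn DatasetDescriptor-class total number of records.
#' @param x a `DatasetDescriptor`.
#' @export
nRecords <- function(x) x@nRecords

#' @describeIn DatasetDescriptor-class sampled first-key-per-chunk list
#'   (`NULL` for unsorted datasets).
#' @export
keySamples <- function(x) x@keySamples

#' @describeIn DatasetDescriptor-class the stored canonical schema text.
#' @export
schemaText <- function(x) x@schemaText

#' @describeIn DatasetDescriptor-class the stored input header text.
#' @export
headerText <- function(x) x@headerText

setMethod("show", "DatasetDescriptor", function(object) {
  cat(sprintf("<dataset '%s': %d records, %d streams, %s, %d bytes stored>\n",
              object@name, as.integer(object@nRecords),
              length(object@streams),
              if (is.null(object@keySamples)) "unsorted" else "sorted",
              as.integer(sum(vapply(object@streams,
                                    function(s) s$totalBytes, 0)))))
})

#' Handle to an on-disk container
#'
#' The container lives in three files sharing a path prefix:
#' `<prefix>.genarc-data` (block data area), `<prefix>.genarc-meta`
#' (settings + block allocation table) and `<prefix>.genarc-ds` (dataset
#' catalog, JSON).  The handle keeps the allocation table and catalog in
#' memory and flushes them after every mutating operation.
#'
#' @slot prefix the path prefix.
#' @slot state internal environment (allocation table, catalog, lock).
#' @export
setClass("GenarcContainer",
         representation(prefix = "character", state = "environment"))

#' @describeIn GenarcContainer-class the container's [ContainerConfig-class].
#' @param x a container handle.
#' @export
containerGeometry <- function(x) x@state$config

#' @describeIn GenarcContainer-class integer vector of per-block states
#'   (0 = free, 1 = reserved, 2 = occupied), big blocks first.
#' @export
blockStates <- function(x) x@state$alloc

setMethod("show", "GenarcContainer", function(object) {
  st <- object@state$alloc
  cat(sprintf("<container '%s': %d/%d blocks occupied, %d reserved, %d datasets>\n",
              object@prefix, sum(st == 2L), length(st), sum(st == 1L),
              length(object@state$catalog)))
})

# ---------------------------------------------------------------------------
# Engine job
# ---------------------------------------------------------------------------

setClassUnion("functionOrNULL", c("function", "NULL"))

#' Compression job configuration
#'
#' @slot schema resolved [RecordSchema-class].
#' @slot plan the derived [StreamPlan-class].
#' @slot adaptors ordered list of `function(record, ordinal)` record
#'   transforms applied before serialization.
#' @slot keyFn optional `function(record)` returning a sort [key][compareKeys];
#'   when set, the input must be sorted by it and first-chunk keys are
#'   sampled into the descriptor.
#' @slot chunkRecords records per chunk (default 50000).
#' @slot workers worker processes for chunk compression.
#' @export
setClass("CompressionJob",
         representation(schema = "RecordSchema", plan = "StreamPlan",
                        adaptors = "list", keyFn = "functionOrNULL",
                        chunkRecords = "numeric", workers = "numeric"),
         validity = function(object) {
           if (object@chunkRecords < 1) return("chunkRecords must be >= 1")
           if (object@workers < 1) return("workers must be >= 1")
           TRUE
         })

#' @param schema a resolved [RecordSchema-class].
#' @param adaptors list of record transforms.
#' @param keyFn optional key function.
#' @param chunkRecords records per chunk.
#' @param workers number of chunk-compression workers.
#' @rdname CompressionJob-class
#' @export
compressionJob <- function(schema, adaptors = list(), keyFn = NULL,
                           chunkRecords = 50000, workers = 1) {
  new("CompressionJob", schema = schema, plan = planStreams(schema),
      adaptors = adaptors, keyFn = keyFn,
      chunkRecords = as.numeric(chunkRecords), workers = as.numeric(workers))
}

#' Fixture generator configuration
#'
#' All fixture generators are pure functions of this configuration; the
#' randomness comes from a splitmix64 generator fixed in the package so
#' outputs are bit-identical across platforms and R versions.
#'
#' @slot seed integer seed (non-negative, below 2^53).
#' @slot nRecords number of records to generate.
#' @slot readLength length-2 range of read lengths.
#' @slot nContigs,contigLength reference geometry.
#' @slot errorRate per-base substitution rate.
#' @slot indelRate per-read probability of one indel.
#' @slot softclipRate per-read probability of a leading soft-clip.
#' @slot fracUnmapped fraction of unmapped records.
#' @slot sorted emit SAM sorted by (reference index, position)?
#' @slot nameStyle `"plain"` or `"illumina"` read-name style.
#' @export
setClass("GeneratorConfig",
         representation(seed = "numeric", nRecords = "numeric",
                        readLength = "numeric", nContigs = "numeric",
                        contigLength = "numeric", errorRate = "numeric",
                        indelRate = "numeric", softclipRate = "numeric",
                        fracUnmapped = "numeric", sorted = "logical",
                        nameStyle = "character"),
         validity = function(object) {
           rates <- c(object@errorRate, object@indelRate,
                      object@softclipRate, object@fracUnmapped)
           if (any(rates < 0 | rates > 1)) return("rates must be in [0, 1]")
           if (any(object@readLength < 1) || object@contigLength < 1)
             return("lengths must be >= 1")
           if (length(object@readLength) != 2 ||
               object@readLength[1] > object@readLength[2])
             return("readLength must be a nondecreasing length-2 range")
           if (!object@nameStyle %in% c("plain", "illumina"))
             return("nameStyle must be 'plain' or 'illumina'")
           TRUE
         })

#' @param seed,nRecords,readLength,nContigs,contigLength,errorRate,indelRate,softclipRate,fracUnmapped,sorted,nameStyle see slots.
#' @rdname GeneratorConfig-class
#' @export
generatorConfig <- function(seed = 1, nRecords = 1000,
                            readLength = c(100, 100), nContigs = 2,
                            contigLength = 100000, errorRate = 0.005,
                            indelRate = 0.02, softclipRate = 0.05,
                            fracUnmapped = 0.02, sorted = TRUE,
                            nameStyle = "plain") {
  new("GeneratorConfig", seed = as.numeric(seed),
      nRecords = as.numeric(nRecords), readLength = as.numeric(readLength),
      nContigs = as.numeric(nContigs), contigLength = as.numeric(contigLength),
      errorRate = as.numeric(errorRate), indelRate = as.numeric(indelRate),
      softclipRate = as.numeric(softclipRate),
      fracUnmapped = as.numeric(fracUnmapped), sorted = sorted,
      nameStyle = nameStyle)
}

# ---------------------------------------------------------------------------
# Structural equality of schema trees (positions and nothing else ignored)
# ---------------------------------------------------------------------------

#' Structural equality of type nodes, fields, documents
#'
#' Compares schema structure (names, kinds, codecs) while ignoring source
#' positions, so that `parseSchema(renderSchema(doc))` compares equal to
#' `doc`.
#'
#' @param a,b type nodes, [FieldDef-class]s or [SchemaDoc-class]s.
#' @return logical(1).
#' @export
typeEqual <- function(a, b) {
  if (!identical(class(a), class(b))) return(FALSE)
  if (is(a, "PrimitiveType")) return(a@kind == b@kind)
  if (is(a, "NamedRefType")) return(a@name == b@name)
  if (is(a, "FixedArrayType"))
    return(a@length == b@length && typeEqual(a@element, b@element))
  if (is(a, "VarArrayType")) return(typeEqual(a@element, b@element))
  if (is(a, "RecordType")) return(.fieldsEqual(a@fields, b@fields))
  if (is(a, "UnionType")) return(.fieldsEqual(a@alternatives, b@alternatives))
  FALSE
}

.codecEqual <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  a@method == b@method &&
    ((is.na(a@level) && is.na(b@level)) ||
     (!is.na(a@level) && !is.na(b@level) && a@level == b@level))
}

.fieldsEqual <- function(fa, fb) {
  if (length(fa) != length(fb)) return(FALSE)
  for (i in seq_along(fa)) {
    if (fa[[i]]@name != fb[[i]]@name) return(FALSE)
    if (!.codecEqual(fa[[i]]@codec, fb[[i]]@codec)) return(FALSE)
    if (!typeEqual(fa[[i]]@type, fb[[i]]@type)) return(FALSE)
  }
  TRUE
}

#' @rdname typeEqual
#' @export
schemaDocEqual <- function(a, b) {
  if (!identical(names(a@defs), names(b@defs))) return(FALSE)
  for (nm in names(a@defs))
    if (!typeEqual(a@defs[[nm]], b@defs[[nm]])) return(FALSE)
  a@entryName == b@entryName && typeEqual(a@entry, b@entry)
}
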