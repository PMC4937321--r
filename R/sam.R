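# SAM parsing/unparsing, stock schemas and the genomic position key.
#
# Optional fields (tags) are kept as raw tab-joined text, never decoded:
# re-encoding a float or array tag could change its spelling and break the
# byte-exact round-trip guarantee.

#' Stock SAM schema text
#'
#' One stream (pair) per mandatory field, a single raw-text stream for the
#' optional fields, bzip2 for base/quality payloads and gzip elsewhere.
#' With `withRef = TRUE` the sequence field becomes a union of a verbatim
#' byte string and a list of differences against a reference window
#' (see [refEncode()]), which is how the reference-based SAM compressor
#' stores mapped reads.
#'
#' @param withRef use the reference-based sequence union?
#' @return character(1) schema source.
#' @export
samSchemaText <- function(withRef = FALSE) {
  seqField <- if (withRef)
    paste0("  seq: union {\n",
           "    verbatim: dna @bzip2(9);\n",
           "    diffs: DiffOp[] @gzip(6);\n",
           "  };\n")
  else "  seq: dna @bzip2(9);\n"
  paste0(if (withRef)
    "DiffOp = {\n  off: u32;\n  kind: u8;\n  bases: dna;\n};\n" else "",
    "@record Alignment {\n",
    "  qname: string @gzip(6);\n",
    "  flag: u16 @gzip(6);\n",
    "  rname: string @gzip(6);\n",
    "  pos: u32 @gzip(6);\n",
    "  mapq: u8 @gzip(6);\n",
    "  cigar: string @gzip(6);\n",
    "  rnext: string @gzip(6);\n",
    "  pnext: u32 @gzip(6);\n",
    "  tlen: i64 @gzip(6);\n",
    seqField,
    "  qual: qual @bzip2(9);\n",
    "  tags: string @gzip(6);\n",
    "}\n")
}

.CIGAR_RE <- "[0-9]+[MIDNSHP=X]"

# query lengths consumed by a vector of CIGAR strings ("*" -> NA)
.cigarQueryLengths <- function(cigars) {
  out <- rep(NA_real_, length(cigars))
  idx <- which(cigars != "*")
  if (!length(idx)) return(out)
  mm <- gregexpr(.CIGAR_RE, cigars[idx])
  parts <- regmatches(cigars[idx], mm)
  whole <- vapply(parts, function(p) paste(p, collapse = ""), "")
  bad <- which(whole != cigars[idx])
  if (length(bad))
    stopData("malformed CIGAR '%s' (record %d)", cigars[idx][bad[1]],
             idx[bad[1]])
  out[idx] <- vapply(parts, function(p) {
    op <- substring(p, nchar(p))
    sum(as.numeric(substring(p, 1, nchar(p) - 1))[op %in%
                                                  c("M", "I", "S", "=", "X")])
  }, 0)
  out
}

#' Parse SAM text
#'
#' The leading run of `@` lines is captured verbatim as the header.  Each
#' alignment line becomes a schema-shaped record:
#' `list(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
#' qual, tags)` with `tags` the raw tab-joined optional-field text (`""`
#' when absent).  Sequence/quality length agreement and CIGAR/sequence
#' consistency are validated.
#'
#' @param text full file content (LF line endings).
#' @return `list(header = <verbatim @ lines>, records = <list>)`.
#' @export
parseSam <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("\r", text, fixed = TRUE))
    stopData("SAM input contains CR characters; only LF line endings are supported")
  if (!nzchar(text)) return(list(header = "", records = list()))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  isHdr <- startsWith(lines, "@")
  nHdr <- match(FALSE, isHdr, nomatch = length(lines) + 1L) - 1L
  header <- if (nHdr > 0)
    paste0(paste0(lines[seq_len(nHdr)], "\n"), collapse = "") else ""
  body <- if (nHdr < length(lines)) lines[(nHdr + 1L):length(lines)]
          else character(0)
  if (!length(body)) return(list(header = header, records = list()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 11L)
  if (length(bad))
    stopData("SAM record %d has %d fields (11 mandatory fields required)",
             bad[1], nf[bad[1]])
  fld <- function(i) vapply(parts, `[[`, "", i)
  qname <- fld(1); rname <- fld(3); cigar <- fld(6); rnext <- fld(7)
  seqv <- fld(10); qual <- fld(11)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(fld(i)))
    bad <- which(is.na(v))
    if (length(bad))
      stopData("SAM record %d: non-numeric %s field '%s'",
               bad[1], what, parts[[bad[1]]][[i]])
    v
  }
  flag <- num(2, "FLAG"); pos <- num(4, "POS"); mapq <- num(5, "MAPQ")
  pnext <- num(8, "PNEXT"); tlen <- num(9, "TLEN")
  tags <- vapply(parts, function(p)
    if (length(p) > 11L) paste(p[12:length(p)], collapse = "\t") else "", "")
  ht <- which(nzchar(tags))
  if (length(ht)) {
    pieces <- strsplit(tags[ht], "\t", fixed = TRUE)
    flat <- unlist(pieces, use.names = FALSE)
    okTag <- grepl("^[A-Za-z][A-Za-z0-9]:[AifZHB]:", flat)
    if (!all(okTag)) {
      owner <- rep.int(ht, lengths(pieces))
      stopData("SAM record %d: malformed optional field '%s'",
               owner[which(!okTag)[1]], flat[which(!okTag)[1]])
    }
  }
  both <- seqv != "*" & qual != "*"
  bad <- which(both & nchar(seqv, type = "bytes") !=
                 nchar(qual, type = "bytes"))
  if (length(bad))
    stopData("SAM record %d ('%s'): SEQ and QUAL lengths differ",
             bad[1], qname[bad[1]])
  qlen <- .cigarQueryLengths(cigar)
  chk <- which(!is.na(qlen) & seqv != "*")
  bad <- chk[qlen[chk] != nchar(seqv[chk], type = "bytes")]
  if (length(bad))
    stopData("SAM record %d ('%s'): CIGAR consumes %d query bases but SEQ has %d",
             bad[1], qname[bad[1]], as.integer(qlen[bad[1]]),
             nchar(seqv[bad[1]], type = "bytes"))
  records <- .mapply(function(qn, fl, rn, po, mq, ci, rx, px, tl, sq, qu, tg)
    list(qname = qn, flag = fl, rname = rn, pos = po, mapq = mq, cigar = ci,
         rnext = rx, pnext = px, tlen = tl, seq = sq, qual = qu, tags = tg),
    list(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
         seqv, qual, tags), NULL)
  list(header = header, records = records)
}

#' Unparse SAM records
#'
#' @param records list of SAM record values (`seq` must be a plain string;
#'   apply [refDecodeAdaptor()] first for reference-encoded datasets).
#' @return character vector of alignment lines (no trailing newline).
#' @export
unparseSamRecords <- function(records) {
  if (length(records) == 0L) return(character(0))
  g <- function(f) vapply(records, `[[`, "", f)
  gn <- function(f) .fmtInt(vapply(records, `[[`, 0, f))
  line <- paste(g("qname"), gn("flag"), g("rname"), gn("pos"), gn("mapq"),
                g("cigar"), g("rnext"), gn("pnext"), gn("tlen"),
                g("seq"), g("qual"), sep = "\t")
  tags <- g("tags")
  has <- nzchar(tags)
  line[has] <- paste(line[has], tags[has], sep = "\t")
  line
}

#' @describeIn unparseSamRecords single-record form.
#' @param record one SAM record value.
#' @export
unparseSam <- function(record) unparseSamRecords(list(record))

#' Reference order from a SAM header
#'
#' @param headerText verbatim SAM header text.
#' @return character vector of `@SQ` sequence names, in header order.
#' @export
samHeaderRefs <- function(headerText) {
  if (!nzchar(headerText)) return(character(0))
  lines <- strsplit(headerText, "\n", fixed = TRUE)[[1]]
  sq <- lines[startsWith(lines, "@SQ")]
  sn <- regmatches(sq, regexpr("SN:[^\t]+", sq))
  substring(sn, 4L)
}

#' Genomic position key of a SAM record
#'
#' The key is `(reference index, position)`: the 0-based index of `RNAME`
#' in the reference order, with unmapped records (`RNAME == "*"`) assigned
#' the sentinel index `length(referenceOrder)` so they sort after every
#' mapped record.
#'
#' @param record a SAM record value.
#' @param referenceOrder contig names, e.g. from [samHeaderRefs()].
#' @return a key list for [compareKeys()].
#' @export
samPositionKey <- function(record, referenceOrder) {
  idx <- match(record$rname, referenceOrder)
  if (is.na(idx)) idx <- length(referenceOrder) + 1L
  list(as.numeric(idx - 1L), as.numeric(record$pos))
}

#' @describeIn samPositionKey key-function closure for [compressionJob()] /
#'   [queryRange()].
#' @export
samKeyFun <- function(referenceOrder)
  function(record) samPositionKey(record, referenceOrder)

#' Stock SAM compression job
#'
#' @param reference optional named character vector of contig sequences
#'   (see [readReference()]); when given, read sequences are stored
#'   reference-encoded.
#' @param sorted treat input as coordinate-sorted: validates the order and
#'   samples first-of-chunk keys for [queryRange()].
#' @param referenceOrder contig order for the sort key; defaults to the
#'   reference's names and must be given for `sorted = TRUE` without a
#'   reference.
#' @param adaptors extra record transforms, applied before any
#'   reference encoding.
#' @param chunkRecords,workers see [compressionJob()].
#' @return a [CompressionJob-class].
#' @export
samJob <- function(reference = NULL, sorted = FALSE, referenceOrder = NULL,
                   adaptors = list(), chunkRecords = 50000, workers = 1) {
  withRef <- !is.null(reference)
  if (withRef) adaptors <- c(adaptors, list(refEncodeAdaptor(reference)))
  keyFn <- NULL
  if (sorted) {
    if (is.null(referenceOrder))
      referenceOrder <- names(reference)
    if (is.null(referenceOrder))
      stopUsage("sorted SAM jobs need a referenceOrder (or a reference)")
    keyFn <- samKeyFun(referenceOrder)
  }
  compressionJob(resolveTypes(parseSchema(samSchemaText(withRef))),
                 adaptors = adaptors, keyFn = keyFn,
                 chunkRecords = chunkRecords, workers = workers)
}

#' Read a FASTA reference
#'
#' @param path FASTA file (multi-contig, line-wrapped).
#' @return named character vector of uppercase sequences, in file order.
#' @export
readReference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(out)))
    stopData("duplicate sequence name in reference '%s'", path)
  out
}
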