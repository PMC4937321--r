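# Reference-based sequence encoding.
#
# A mapped read's bases are reconstructable from the reference window
# addressed by (RNAME, POS, CIGAR); only the differences need storing:
# mismatching bases in M/=/X segments and the bases of I (insertion) and
# S (soft-clip) segments.  D/N consume reference only; H/P consume nothing.
# Records that cannot be reference-addressed (unmapped, missing CIGAR,
# contig absent) fall back to storing the sequence verbatim, so encoding is
# total and never loses information.
#
# Encodings are union record values matching the `seq` union of
# samSchemaText(withRef = TRUE):
#   list(alt = 1, value = <seq string>)                     verbatim
#   list(alt = 2, value = list(list(off, kind, bases), .))  diff list
# with off the 0-based query offset, kind 0 = mismatch (single base),
# kind 1 = insert (the segment's bases).

.parseCigarOps <- function(cigar) {
  p <- regmatches(cigar, gregexpr(.CIGAR_RE, cigar))[[1]]
  if (paste(p, collapse = "") != cigar)
    stopData("malformed CIGAR '%s'", cigar)
  list(lens = as.numeric(substring(p, 1, nchar(p) - 1)),
       ops = substring(p, nchar(p)))
}

#' Encode a read sequence against a reference
#'
#' @param record a SAM record value with a plain `seq` string.
#' @param reference named character vector of contig sequences.
#' @return a sequence-encoding union value (see above).
#' @export
refEncode <- function(record, reference) {
  seqv <- record$seq
  if (seqv == "*" || record$cigar == "*" || record$rname == "*" ||
      !record$rname %in% names(reference))
    return(list(alt = 1L, value = seqv))
  pc <- .parseCigarOps(record$cigar)
  qlen <- sum(pc$lens[pc$ops %in% c("M", "I", "S", "=", "X")])
  if (qlen != nchar(seqv))
    stopData("CIGAR '%s' consumes %d query bases but SEQ has %d ('%s')",
             record$cigar, as.integer(qlen), nchar(seqv), record$qname)
  refSeq <- reference[[record$rname]]
  refConsumed <- sum(pc$lens[pc$ops %in% c("M", "D", "N", "=", "X")])
  if (record$pos < 1 || record$pos - 1 + refConsumed > nchar(refSeq))
    stopData("reference window [%d, %d] out of bounds for contig '%s' (%d bases)",
             as.integer(record$pos),
             as.integer(record$pos - 1 + refConsumed),
             record$rname, nchar(refSeq))
  ops <- list()
  qoff <- 0
  roff <- record$pos - 1
  for (i in seq_along(pc$ops)) {
    L <- pc$lens[i]
    op <- pc$ops[i]
    if (op %in% c("M", "=", "X")) {
      rq <- charToRaw(substr(seqv, qoff + 1, qoff + L))
      rr <- charToRaw(substr(refSeq, roff + 1, roff + L))
      d <- which(rq != rr)
      for (j in d)
        ops[[length(ops) + 1L]] <-
          list(off = qoff + j - 1, kind = 0, bases = rawToChar(rq[j]))
      qoff <- qoff + L
      roff <- roff + L
    } else if (op %in% c("I", "S")) {
      ops[[length(ops) + 1L]] <-
        list(off = qoff, kind = 1,
             bases = substr(seqv, qoff + 1, qoff + L))
      qoff <- qoff + L
    } else if (op %in% c("D", "N")) {
      roff <- roff + L
    }
    # H and P consume neither query nor stored sequence
  }
  list(alt = 2L, value = ops)
}

#' Decode a sequence encoding back to the read bases
#'
#' Exact inverse of [refEncode()] given the record's coordinates.
#'
#' @param encoding the union value produced by [refEncode()].
#' @param record the SAM record value providing `rname`, `pos`, `cigar`.
#' @param reference named character vector of contig sequences.
#' @return the sequence string.
#' @export
refDecode <- function(encoding, record, reference) {
  if (encoding$alt == 1L) return(encoding$value)
  pc <- .parseCigarOps(record$cigar)
  qlen <- sum(pc$lens[pc$ops %in% c("M", "I", "S", "=", "X")])
  refSeq <- reference[[record$rname]]
  if (is.null(refSeq))
    stopData("contig '%s' not in reference", record$rname)
  out <- raw(qlen)
  qoff <- 0
  roff <- record$pos - 1
  for (i in seq_along(pc$ops)) {
    L <- pc$lens[i]
    op <- pc$ops[i]
    if (op %in% c("M", "=", "X")) {
      out[(qoff + 1):(qoff + L)] <-
        charToRaw(substr(refSeq, roff + 1, roff + L))
      qoff <- qoff + L
      roff <- roff + L
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + L
    } else if (op %in% c("D", "N")) {
      roff <- roff + L
    }
  }
  for (o in encoding$value) {
    bases <- charToRaw(o$bases)
    out[(o$off + 1):(o$off + length(bases))] <- bases
  }
  rawToChar(out)
}

#' Reference-encoding adaptors
#'
#' `refEncodeAdaptor` turns each record's `seq` into its encoding before
#' serialization (compression side); `refDecodeAdaptor` is its declared
#' inverse for the decompression side.
#'
#' @param reference named character vector of contig sequences.
#' @return `function(record, ordinal)`.
#' @export
refEncodeAdaptor <- function(reference) {
  force(reference)
  function(record, ordinal) {
    record$seq <- refEncode(record, reference)
    record
  }
}

#' @rdname refEncodeAdaptor
#' @export
refDecodeAdaptor <- function(reference) {
  force(reference)
  function(record, ordinal) {
    record$seq <- refDecode(record$seq, record, reference)
    record
  }
}
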