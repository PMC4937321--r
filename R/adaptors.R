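# Lossy adaptors: Illumina-style 8-level quality binning and "Max"
# stripping of read names / optional fields.  Adaptors are record-to-record
# transforms with signature function(record, ordinal); they run on the
# compression side only (no inverse exists for deliberate information loss).

.QUAL_BIN_BREAKS <- c(0, 2, 10, 20, 25, 30, 35, 40)
.QUAL_BIN_VALUES <- c(0, 6, 15, 22, 27, 33, 37, 40)

#' Bin a Phred quality score to the Illumina 8-level scheme
#'
#' The RTA binning table: 0-1 -> 0, 2-9 -> 6, 10-19 -> 15, 20-24 -> 22,
#' 25-29 -> 27, 30-34 -> 33, 35-39 -> 37, >= 40 -> 40.  Over the usual
#' Phred range 0-41 the image has exactly 8 values; the map is idempotent.
#'
#' @param q vector of Phred integers (>= 0).
#' @return binned Phred integers.
#' @export
binQuality <- function(q) {
  if (any(q < 0)) stopData("negative Phred quality score")
  .QUAL_BIN_VALUES[findInterval(q, .QUAL_BIN_BREAKS)]
}

# Phred+33 character transliteration table for chartr()
.qualCharFrom <- local({
  f <- NULL
  function() {
    if (is.null(f)) f <<- intToUtf8(33:126)
    f
  }
})
.qualCharTo <- local({
  t <- NULL
  function() {
    if (is.null(t)) t <<- intToUtf8(33 + binQuality(0:93))
    t
  }
})

#' Quality-binning adaptor
#'
#' Maps every quality byte through [binQuality()] in Phred space
#' (Phred+33 encoding); all other fields are untouched.  A SAM record whose
#' quality is the absent marker `"*"` passes through unchanged.  Idempotent.
#'
#' @param record a FASTQ or SAM record value.
#' @param ordinal record ordinal (unused; adaptor signature).
#' @return the record with binned qualities.
#' @export
adaptorBinQualities <- function(record, ordinal = NA_integer_) {
  q <- record$qual
  if (identical(q, "*") && !is.null(record$rname)) return(record)
  r <- charToRaw(q)
  if (any(r < as.raw(33)))
    stopData("quality byte %d below 33: not Phred+33",
             min(as.integer(r)))
  record$qual <- chartr(.qualCharFrom(), .qualCharTo(), q)
  record
}

#' "Max" stripping adaptor
#'
#' Discards the fields that dominate lossless size but carry no analysis
#' signal: for SAM records the read name becomes `"*"` and the optional
#' fields are dropped; for FASTQ records the title is replaced by the
#' record's running ordinal.  Irreversible; applying it twice equals
#' applying it once.
#'
#' @param record a FASTQ or SAM record value.
#' @param ordinal 1-based record ordinal (used as the FASTQ placeholder
#'   title).
#' @return the stripped record.
#' @export
adaptorMaxStrip <- function(record, ordinal = NA_integer_) {
  if (!is.null(record$qname)) {
    record$qname <- "*"
    record$tags <- ""
  } else {
    record$title <- .fmtInt(ordinal)
  }
  record
}
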