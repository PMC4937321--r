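#' genarc: schema-driven columnar compressed storage for genomic records
#'
#' A record-type definition written in a small meta-language is decomposed
#' into independently compressed column streams stored in a block-allocated
#' container file with per-block checksums; sorted datasets support
#' bisection range queries over sampled keys.  Stock FASTQ and SAM
#' compressors, lossy adaptors and reference-based sequence encoding are
#' built on the same engine.
#'
#' @useDynLib genarc, .registration = TRUE
#' @importFrom jsonlite read_json write_json toJSON
#' @importFrom parallel mclapply
#' @importFrom stats setNames
#' @keywords internal
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  .registerBuiltinCodecs()
}
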