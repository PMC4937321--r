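# FASTQ parsing/unparsing and the stock FASTQ schema.
#
# Records are schema-shaped named lists: title (no leading "@"), seq,
# plus (text after "+", preserved verbatim), qual (Phred+33).  Round trips
# are byte-exact on canonical LF inputs.

#' Stock FASTQ schema text
#'
#' One variable-length byte-string stream pair per field; read names
#' gzip-compressed, bases and qualities bzip2-compressed.
#'
#' @return character(1) schema source.
#' @export
fastqSchemaText <- function() {
  paste0("@record Fastq {\n",
         "  title: string @gzip(6);\n",
         "  seq: dna @bzip2(9);\n",
         "  plus: string @gzip(6);\n",
         "  qual: qual @bzip2(9);\n",
         "}\n")
}

#' Parse FASTQ text
#'
#' @param text full file content (LF line endings; CR is rejected).
#' @return `list(header = "", records = <list>)`; each record is
#'   `list(title, seq, plus, qual)`.
#' @export
parseFastq <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("\r", text, fixed = TRUE))
    stopData("FASTQ input contains CR characters; only LF line endings are supported")
  if (!nzchar(text)) return(list(header = "", records = list()))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  n <- length(lines)
  if (n %% 4L != 0L)
    stopData("truncated FASTQ record: %d trailing line(s)", n %% 4L)
  i1 <- seq.int(1L, n, 4L)
  heads <- lines[i1]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    stopData("FASTQ record %d does not start with '@' (line %d)",
             bad[1], i1[bad[1]])
  titles <- substring(heads, 2L)
  bad <- which(!nzchar(titles))
  if (length(bad))
    stopData("empty FASTQ read name (line %d)", i1[bad[1]])
  seqs <- lines[i1 + 1L]
  plusLines <- lines[i1 + 2L]
  bad <- which(!startsWith(plusLines, "+"))
  if (length(bad))
    stopData("FASTQ record %d: separator line does not start with '+' (line %d)",
             bad[1], i1[bad[1]] + 2L)
  quals <- lines[i1 + 3L]
  bad <- which(nchar(seqs, type = "bytes") != nchar(quals, type = "bytes"))
  if (length(bad))
    stopData("FASTQ record %d ('%s'): sequence and quality lengths differ (%d vs %d)",
             bad[1], titles[bad[1]],
             nchar(seqs[bad[1]], type = "bytes"),
             nchar(quals[bad[1]], type = "bytes"))
  records <- .mapply(function(t, s, p, q)
    list(title = t, seq = s, plus = p, qual = q),
    list(titles, seqs, substring(plusLines, 2L), quals), NULL)
  list(header = "", records = records)
}

#' Unparse FASTQ records
#'
#' @param records list of FASTQ record values.
#' @return character vector, one 4-line block per record (no trailing
#'   newline; the engine adds the line terminator).
#' @export
unparseFastqRecords <- function(records) {
  if (length(records) == 0L) return(character(0))
  t <- vapply(records, `[[`, "", "title")
  s <- vapply(records, `[[`, "", "seq")
  p <- vapply(records, `[[`, "", "plus")
  q <- vapply(records, `[[`, "", "qual")
  paste0("@", t, "\n", s, "\n+", p, "\n", q)
}

#' @describeIn unparseFastqRecords single-record form (4 lines as one string).
#' @param record one FASTQ record value.
#' @export
unparseFastq <- function(record) unparseFastqRecords(list(record))

#' Stock FASTQ compression job
#'
#' @param adaptors record transforms (e.g. [adaptorBinQualities()]).
#' @param chunkRecords,workers see [compressionJob()].
#' @return a [CompressionJob-class].
#' @export
fastqJob <- function(adaptors = list(), chunkRecords = 50000, workers = 1) {
  compressionJob(resolveTypes(parseSchema(fastqSchemaText())),
                 adaptors = adaptors, chunkRecords = chunkRecords,
                 workers = workers)
}
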