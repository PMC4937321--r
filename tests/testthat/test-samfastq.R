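# FASTQ/SAM parsing, genomic keys, lossy adaptors, reference encoding.

test_that("minimal FASTQ round-trips byte-identically, plus-line preserved", {
  txt <- "@r1\nACGT\n+\nIIII\n"
  p <- parseFastq(txt)
  expect_identical(p$header, "")
  expect_identical(p$records[[1]]$title, "r1")
  expect_identical(paste0(unparseFastqRecords(p$records), "\n"), txt)
  # "+r1" content survives
  txt2 <- "@r1\nAC\n+r1 extra\n!~\n"
  p2 <- parseFastq(txt2)
  expect_identical(p2$records[[1]]$plus, "r1 extra")
  expect_identical(paste0(unparseFastq(p2$records[[1]]), "\n"), txt2)
})

test_that("FASTQ validation: length mismatch, truncation, CR", {
  expect_error(parseFastq("@r\nACG\n+\nII\n"), class = "genarcDataError")
  expect_error(parseFastq("@r\nACG\n+\n"), class = "genarcDataError")
  expect_error(parseFastq("@r\r\nACG\r\n+\r\nIII\r\n"),
               class = "genarcDataError")
  expect_error(parseFastq("@\nA\n+\nI\n"), class = "genarcDataError")
})

test_that("generated FASTQ round-trips through parse/unparse at scale", {
  fq <- generateFastq(generatorConfig(seed = 41, nRecords = 10000,
                                      readLength = c(60, 100),
                                      nameStyle = "illumina"))
  p <- parseFastq(fq)
  expect_length(p$records, 10000L)
  expect_identical(paste0(paste0(unparseFastqRecords(p$records), "\n"),
                          collapse = ""), fq)
})

test_that("minimal unmapped SAM record round-trips", {
  line <- "r\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  p <- parseSam(paste0(line, "\n"))
  expect_identical(p$header, "")
  expect_identical(unparseSamRecords(p$records), line)
})

test_that("SAM tags survive as raw text and the header verbatim", {
  txt <- paste0("@HD\tVN:1.6\tSO:coordinate\n@SQ\tSN:chr1\tLN:100\n",
                "r1\t0\tchr1\t5\t60\t4M\t*\t0\t0\tACGT\tIIII\t",
                "NM:i:2\tXA:Z:foo,bar;\tZf:f:1.5\n")
  p <- parseSam(txt)
  expect_identical(p$header, "@HD\tVN:1.6\tSO:coordinate\n@SQ\tSN:chr1\tLN:100\n")
  expect_identical(p$records[[1]]$tags, "NM:i:2\tXA:Z:foo,bar;\tZf:f:1.5")
  expect_identical(paste0(p$header,
                          paste0(unparseSamRecords(p$records), "\n")), txt)
})

test_that("SAM validation: field count, numeric fields, tags, cigar", {
  expect_error(parseSam("r\t0\tchr1\t1\t60\t*\t*\t0\t0\tAC\n"),
               class = "genarcDataError")        # 10 fields
  expect_error(parseSam("r\tX\tchr1\t1\t60\t*\t*\t0\t0\tAC\tII\n"),
               class = "genarcDataError")        # non-numeric flag
  expect_error(parseSam("r\t0\tchr1\t1\t60\t*\t*\t0\t0\tAC\tIII\n"),
               class = "genarcDataError")        # seq/qual length
  expect_error(parseSam("r\t0\tchr1\t1\t60\t3M\t*\t0\t0\tAC\tII\n"),
               class = "genarcDataError")        # cigar consumes 3 vs 2
  expect_error(parseSam("r\t0\tchr1\t1\t60\t2M\t*\t0\t0\tAC\tII\tNM=2\n"),
               class = "genarcDataError")        # malformed tag
})

test_that("generated SAM with tags round-trips byte-identically at scale", {
  gc0 <- generatorConfig(seed = 43, nRecords = 5000, nameStyle = "illumina")
  sam <- generateSam(generateReference(gc0), gc0)
  p <- parseSam(sam)
  expect_identical(paste0(p$header,
                          paste0(unparseSamRecords(p$records), "\n",
                                 collapse = "")), sam)
})

test_that("genomic position keys order contigs by header and unmapped last", {
  refOrder <- c("chr1", "chr2")
  r1 <- list(rname = "chr1", pos = 1)
  r2 <- list(rname = "chr2", pos = 7)
  un <- list(rname = "*", pos = 0)
  expect_identical(samPositionKey(r1, refOrder), list(0, 1))
  expect_identical(samPositionKey(r2, refOrder), list(1, 7))
  expect_identical(samPositionKey(un, refOrder)[[1]], 2)
  expect_lt(compareKeys(samPositionKey(r2, refOrder),
                        samPositionKey(un, refOrder)), 0L)
})

test_that("coordinate-sorted fixtures yield nondecreasing keys", {
  gc0 <- generatorConfig(seed = 44, nRecords = 400, nContigs = 3)
  sam <- generateSam(generateReference(gc0), gc0)
  refOrder <- samHeaderRefs(parseSam(sam)$header)
  keys <- lapply(parseSam(sam)$records, samKeyFun(refOrder))
  ok <- vapply(seq_len(length(keys) - 1), function(i)
    compareKeys(keys[[i]], keys[[i + 1]]) <= 0, TRUE)
  expect_true(all(ok))
})

test_that("quality binning maps the full Phred range onto exactly 8 values", {
  expect_identical(binQuality(0), 0)
  expect_identical(binQuality(29), 27)
  expect_identical(binQuality(41), 40)
  img <- unique(binQuality(0:41))
  expect_length(img, 8L)
  expect_setequal(img, c(0, 6, 15, 22, 27, 33, 37, 40))
  # idempotent on its own image
  expect_identical(binQuality(img), img)
  expect_error(binQuality(-1), class = "genarcDataError")
})

test_that("the binning adaptor touches only qualities and is idempotent", {
  rec <- list(title = "r", seq = "ACGTA",
              plus = "", qual = rawToChar(as.raw(33 + c(0, 12, 29, 41, 93))))
  out <- adaptorBinQualities(rec, 1)
  expect_identical(out$seq, rec$seq)
  expect_identical(out$title, rec$title)
  expect_identical(utf8ToInt(out$qual) - 33, c(0, 15, 27, 40, 40))
  expect_identical(adaptorBinQualities(out, 1), out)
  # distinct symbols after binning never exceed 8
  fq <- generateFastq(generatorConfig(seed = 45, nRecords = 300))
  p <- parseFastq(fq)
  binned <- lapply(seq_along(p$records), function(i)
    adaptorBinQualities(p$records[[i]], i))
  syms <- unique(strsplit(paste(vapply(binned, `[[`, "", "qual"),
                                collapse = ""), "")[[1]])
  expect_lte(length(syms), 8L)
  # raw input spans enough symbols for the test to be meaningful
  raw_ <- unique(strsplit(paste(vapply(p$records, `[[`, "", "qual"),
                                collapse = ""), "")[[1]])
  expect_gte(length(raw_), 20L)
})

test_that("binning leaves SAM '*' qualities alone and rejects non-Phred+33", {
  un <- list(qname = "r", flag = 4, rname = "*", pos = 0, mapq = 0,
             cigar = "*", rnext = "*", pnext = 0, tlen = 0, seq = "*",
             qual = "*", tags = "")
  expect_identical(adaptorBinQualities(un, 1), un)
  bad <- list(title = "r", seq = "A", plus = "", qual = rawToChar(as.raw(20)))
  expect_error(adaptorBinQualities(bad, 1), class = "genarcDataError")
})

test_that("max stripping blanks SAM names/tags and renumbers FASTQ titles", {
  sam <- list(qname = "long.read.name/1", flag = 0, rname = "chr1", pos = 3,
              mapq = 60, cigar = "2M", rnext = "*", pnext = 0, tlen = 0,
              seq = "AC", qual = "II", tags = "NM:i:0\tRG:Z:x")
  s1 <- adaptorMaxStrip(sam, 17)
  expect_identical(s1$qname, "*")
  expect_identical(s1$tags, "")
  expect_length(strsplit(unparseSamRecords(list(s1)), "\t")[[1]], 11L)
  expect_identical(adaptorMaxStrip(s1, 17), s1)
  fq <- list(title = "machine:1:2:3", seq = "A", plus = "", qual = "I")
  expect_identical(adaptorMaxStrip(fq, 5)$title, "5")
})

test_that("max stripping shrinks the stored size on a name-rich fixture", {
  fq <- generateFastq(generatorConfig(seed = 46, nRecords = 2000,
                                      nameStyle = "illumina"))
  stored <- function(adaptors) {
    h <- createContainer(tmpPrefix(), containerConfig(262144, 4096, 8, 64))
    on.exit(closeContainer(h))
    d <- compressDataset(h, "fq", fq, parseFastq,
                         fastqJob(adaptors = adaptors, chunkRecords = 1000))
    sum(vapply(d@streams, function(s) s$totalBytes, 0))
  }
  expect_lt(stored(list(adaptorMaxStrip)), stored(list()))
})

test_that("reference encoding: perfect match, point substitution, fallback", {
  ref <- c(chr1 = strrep("ACGT", 10))
  rec <- list(qname = "r", flag = 0, rname = "chr1", pos = 5, mapq = 60,
              cigar = "10M", rnext = "*", pnext = 0, tlen = 0,
              seq = substr(ref[["chr1"]], 5, 14), qual = strrep("I", 10),
              tags = "")
  enc <- refEncode(rec, ref)
  expect_identical(enc$alt, 2L)
  expect_length(enc$value, 0L)
  expect_identical(refDecode(enc, rec, ref), rec$seq)

  sub <- rec
  substr(sub$seq, 4, 4) <- "G"   # ref has "T" at query offset 3
  enc2 <- refEncode(sub, ref)
  expect_length(enc2$value, 1L)
  expect_identical(enc2$value[[1]], list(off = 3, kind = 0, bases = "G"))
  expect_identical(refDecode(enc2, sub, ref), sub$seq)

  # unmapped and unknown-contig records fall back to verbatim
  un <- list(qname = "u", flag = 4, rname = "*", pos = 0, mapq = 0,
             cigar = "*", rnext = "*", pnext = 0, tlen = 0, seq = "ACGT",
             qual = "IIII", tags = "")
  expect_identical(refEncode(un, ref), list(alt = 1L, value = "ACGT"))
  offref <- rec; offref$rname <- "chrX"
  expect_identical(refEncode(offref, ref)$alt, 1L)
})

test_that("insertions, deletions and soft-clips encode as documented ops", {
  ref <- c(c1 = "AAAACCCCGGGGTTTT")
  # 2S3M2I3M1D2M: clip "GG", M ref[1..3]="AAA", ins "TT", M ref[4..6]="ACC",
  # del skips ref[7], M ref[8..9]="CG" read as "CT" (one mismatch)
  rec <- list(qname = "r", flag = 0, rname = "c1", pos = 1, mapq = 60,
              cigar = "2S3M2I3M1D2M", rnext = "*", pnext = 0, tlen = 0,
              seq = paste0("GG", "AAA", "TT", "ACC", "CT"), qual = "",
              tags = "")
  rec$qual <- strrep("I", nchar(rec$seq))
  enc <- refEncode(rec, ref)
  expect_identical(enc$alt, 2L)
  expect_identical(lapply(enc$value, `[[`, "kind"), list(1, 1, 0))
  expect_identical(enc$value[[1]], list(off = 0, kind = 1, bases = "GG"))
  expect_identical(enc$value[[2]], list(off = 5, kind = 1, bases = "TT"))
  expect_identical(enc$value[[3]], list(off = 11, kind = 0, bases = "T"))
  expect_identical(refDecode(enc, rec, ref), rec$seq)
})

test_that("decode(encode(r)) recovers every generated read exactly", {
  gc0 <- generatorConfig(seed = 47, nRecords = 2000, errorRate = 0.02,
                         indelRate = 0.3, softclipRate = 0.3,
                         fracUnmapped = 0.05)
  refTxt <- generateReference(gc0)
  ref <- genarc:::.refFromFastaText(refTxt)
  recs <- parseSam(generateSam(refTxt, gc0))$records
  ok <- vapply(recs, function(r)
    identical(refDecode(refEncode(r, ref), r, ref), r$seq), TRUE)
  expect_true(all(ok))
})

test_that("cigar/sequence inconsistency is an error, not a fallback", {
  ref <- c(chr1 = strrep("A", 50))
  bad <- list(qname = "r", flag = 0, rname = "chr1", pos = 1, mapq = 60,
              cigar = "5M", rnext = "*", pnext = 0, tlen = 0, seq = "AAA",
              qual = "III", tags = "")
  expect_error(refEncode(bad, ref), class = "genarcDataError")
  oob <- bad; oob$seq <- strrep("A", 5); oob$pos <- 48
  expect_error(refEncode(oob, ref), class = "genarcDataError")
})
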