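# Deterministic synthetic-data generators.  Every draw comes from the
# package's fixed splitmix64 generator (never R's RNG), so output is
# bit-identical across runs, platforms and R versions.  Per-object
# substreams are derived arithmetically from the seed so generation order
# never shifts between records.

.BASES <- c("A", "C", "G", "T")

.deriveSeed <- function(seed, tag) (seed * 1000003 + tag) %% 2^53

#' Generate a random reference genome as FASTA text
#'
#' Uniform ACGT contigs named `chr1..chrN`, wrapped at 70 columns.
#'
#' @param config a [generatorConfig()]; uses `seed`, `nContigs`,
#'   `contigLength`.
#' @return FASTA text (possibly `""` for zero contigs).
#' @export
generateReference <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  n <- as.integer(config@nContigs)
  if (n == 0L) return("")
  out <- character(n)
  for (c_i in seq_len(n)) {
    u <- .rngUniform(.deriveSeed(config@seed, c_i), config@contigLength)
    s <- paste(.BASES[1L + floor(u * 4)], collapse = "")
    L <- nchar(s)
    starts <- seq.int(1L, L, 70L)
    wrapped <- paste(substring(s, starts, pmin(starts + 69L, L)),
                     collapse = "\n")
    out[c_i] <- paste0(">chr", c_i, "\n", wrapped, "\n")
  }
  paste(out, collapse = "")
}

.refFromFastaText <- function(text) {
  if (!nzchar(text)) return(character(0))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  hdr <- which(startsWith(lines, ">"))
  nms <- sub("^>([^ \t]+).*$", "\\1", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), "")
  names(seqs) <- nms
  toupper(seqs)
}

.readName <- function(config, i, u2) {
  if (config@nameStyle == "illumina")
    sprintf("SIM01:1:FCX:1:%d:%d:%d", 1000L + i %% 7L,
            1L + as.integer(floor(u2[1] * 25000)),
            1L + as.integer(floor(u2[2] * 25000)))
  else paste0("read_", i)
}

#' Generate FASTQ text
#'
#' Uniform bases; qualities uniform on Phred 0..41 (so all 42 symbols occur
#' in any sizeable file and lossy binning is observable); read lengths
#' uniform in `config@readLength`.
#'
#' @param config a [generatorConfig()].
#' @return FASTQ text.
#' @export
generateFastq <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  n <- as.integer(config@nRecords)
  if (n == 0L) return("")
  lmin <- config@readLength[1]; lmax <- config@readLength[2]
  u1 <- .rngUniform(.deriveSeed(config@seed, 7001), n)
  lens <- lmin + floor(u1 * (lmax - lmin + 1))
  total <- sum(lens)
  ub <- .rngUniform(.deriveSeed(config@seed, 7002), total)
  allBases <- paste(.BASES[1L + floor(ub * 4)], collapse = "")
  uq <- .rngUniform(.deriveSeed(config@seed, 7003), total)
  allQuals <- intToUtf8(33L + as.integer(floor(uq * 42)))
  un <- .rngUniform(.deriveSeed(config@seed, 7004), 2L * n)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  seqs <- substring(allBases, starts, ends)
  quals <- substring(allQuals, starts, ends)
  titles <- vapply(seq_len(n), function(i)
    .readName(config, i, un[c(2L * i - 1L, 2L * i)]), "")
  paste0("@", titles, "\n", seqs, "\n+\n", quals, "\n", collapse = "")
}

#' Generate SAM text from a reference
#'
#' Reads are sampled from the reference with per-base substitutions, an
#' optional mid-read indel and an optional leading soft-clip; CIGAR and SEQ
#' are always mutually consistent and every mapped read reference-decodes
#' exactly.  A configured fraction of records is unmapped (`FLAG 4`, `*`
#' placeholder fields).  With `config@sorted`, mapped records are emitted in
#' nondecreasing (reference index, position) order, unmapped records last,
#' and the header carries `SO:coordinate`.
#'
#' @param referenceText FASTA text from [generateReference()].
#' @param config a [generatorConfig()].
#' @return SAM text (header + alignment lines).
#' @export
generateSam <- function(referenceText, config) {
  stopifnot(is(config, "GeneratorConfig"))
  ref <- .refFromFastaText(referenceText)
  if (length(ref) == 0L) stopUsage("generateSam needs a nonempty reference")
  n <- as.integer(config@nRecords)
  nUn <- as.integer(round(config@fracUnmapped * n))
  nMap <- n - nUn
  lmin <- config@readLength[1]; lmax <- config@readLength[2]
  refLens <- nchar(ref)

  mapped <- vector("list", nMap)
  for (i in seq_len(nMap)) {
    u <- .rngUniform(.deriveSeed(config@seed, 20000 + i), 4 * lmax + 48)
    k <- 0L
    take <- function(m) { v <- u[(k + 1L):(k + m)]; k <<- k + m; v }
    draw <- function() take(1L)
    ci <- 1L + as.integer(floor(draw() * length(ref)))
    L <- as.integer(lmin + floor(draw() * (lmax - lmin + 1)))
    sc1 <- if (draw() < config@softclipRate)
      1L + as.integer(floor(draw() * min(8, L - 2))) else { draw(); 0L }
    hasIndel <- draw() < config@indelRate
    isIns <- draw() < 0.5
    ilen <- 1L + as.integer(floor(draw() * 4))
    core <- L - sc1 - if (hasIndel && isIns) ilen else 0L
    if (core < 2L) { hasIndel <- FALSE; core <- L - sc1 }
    if (hasIndel) {
      m1 <- 1L + as.integer(floor(draw() * (core - 1L)))
      m2 <- core - m1
    } else {
      draw()
      m1 <- core; m2 <- 0L
    }
    refConsumed <- m1 + m2 + if (hasIndel && !isIns) ilen else 0L
    pos <- 1L + as.integer(floor(draw() * (refLens[ci] - refConsumed)))

    # reference-derived segments with substitutions
    mutate <- function(segment) {
      sr <- charToRaw(segment)
      hit <- which(take(length(sr)) < config@errorRate)
      for (h in hit) {
        orig <- match(rawToChar(sr[h]), .BASES)
        shift <- 1L + as.integer(floor(draw() * 3))
        sr[h] <- charToRaw(.BASES[(orig - 1L + shift) %% 4L + 1L])
      }
      rawToChar(sr)
    }
    randBases <- function(m)
      paste(.BASES[1L + as.integer(floor(take(m) * 4))], collapse = "")

    clipSeg <- if (sc1 > 0) randBases(sc1) else ""
    seg1 <- mutate(substr(ref[[ci]], pos, pos + m1 - 1L))
    insSeg <- if (hasIndel && isIns) randBases(ilen) else ""
    seg2 <- if (m2 > 0)
      mutate(substr(ref[[ci]], pos + m1 + (if (hasIndel && !isIns) ilen else 0L),
                    pos + m1 + (if (hasIndel && !isIns) ilen else 0L) + m2 - 1L))
    else ""
    seqv <- paste0(clipSeg, seg1, insSeg, seg2)
    cigar <- paste0(if (sc1 > 0) paste0(sc1, "S") else "",
                    m1, "M",
                    if (hasIndel) paste0(ilen, if (isIns) "I" else "D") else "",
                    if (m2 > 0) paste0(m2, "M") else "")
    qual <- intToUtf8(33L + as.integer(floor(take(nchar(seqv)) * 42)))
    flag <- if (draw() < 0.5) 0 else 16
    mapped[[i]] <- list(
      qname = .readName(config, i, c(draw(), draw())), flag = flag,
      rname = paste0("chr", ci), pos = as.numeric(pos), mapq = 60,
      cigar = cigar, rnext = "*", pnext = 0, tlen = 0, seq = seqv,
      qual = qual,
      tags = paste0("NM:i:", as.integer(floor(draw() * 6)), "\tRG:Z:sim1"))
  }
  if (config@sorted && nMap > 1) {
    ord <- order(vapply(mapped, function(r)
      as.numeric(sub("^chr", "", r$rname)), 0),
      vapply(mapped, `[[`, 0, "pos"))
    mapped <- mapped[ord]
  }
  unmapped <- vector("list", nUn)
  for (i in seq_len(nUn)) {
    u <- .rngUniform(.deriveSeed(config@seed, 60000 + i), 2 * lmax + 16)
    k <- 0L
    take <- function(m) { v <- u[(k + 1L):(k + m)]; k <<- k + m; v }
    L <- as.integer(lmin + floor(take(1L) * (lmax - lmin + 1)))
    seqv <- paste(.BASES[1L + as.integer(floor(take(L) * 4))], collapse = "")
    qual <- intToUtf8(33L + as.integer(floor(take(L) * 42)))
    unmapped[[i]] <- list(
      qname = .readName(config, nMap + i, take(2L)), flag = 4,
      rname = "*", pos = 0, mapq = 0, cigar = "*", rnext = "*", pnext = 0,
      tlen = 0, seq = seqv, qual = qual, tags = "")
  }
  header <- paste0(
    "@HD\tVN:1.6\tSO:", if (config@sorted) "coordinate" else "unsorted",
    "\n",
    paste0("@SQ\tSN:", names(ref), "\tLN:", refLens, "\n", collapse = ""),
    "@RG\tID:sim1\tSM:sim\n")
  records <- c(mapped, unmapped)
  if (length(records) == 0L) return(header)
  paste0(header, paste0(unparseSamRecords(records), "\n", collapse = ""))
}

#' Flip one byte of a file (corruption fixture)
#'
#' XORs the byte at a 0-based offset with a mask; applying the same call
#' twice restores the file, and mask 0 is a no-op.
#'
#' @param path file path.
#' @param offset 0-based byte offset (must be inside the file).
#' @param xorMask integer 0-255.
#' @export
corruptFile <- function(path, offset, xorMask) {
  size <- file.size(path)
  if (is.na(size) || offset < 0 || offset >= size)
    stopUsage("offset %s beyond end of file '%s' (%s bytes)",
              format(offset), path, format(size))
  con <- file(path, "r+b")
  on.exit(close(con))
  seek(con, offset, rw = "read")
  b <- readBin(con, raw(), 1L)
  seek(con, offset, rw = "write")
  writeBin(xor(b, as.raw(xorMask)), con)
  invisible(NULL)
}
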