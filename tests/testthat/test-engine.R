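# Engine: chunked compression, determinism, key sampling, bisection queries.

# scalar 0..5200 -> a 2-component (contig, position) key
.k2 <- function(k) list(k %/% 2500, k %% 2500)

test_that("a zero-record input stores an empty dataset that round-trips", {
  h <- testContainer()
  desc <- compressDataset(h, "empty", "", parseFastq, fastqJob())
  expect_identical(nRecords(desc), 0)
  expect_true(all(vapply(desc@streams, function(s) s$totalBytes, 0) == 0))
  expect_identical(decompressDataset(h, "empty", unparseFastqRecords), "")
})

test_that("record counts are conserved across the chunk index", {
  h <- testContainer()
  fq <- generateFastq(generatorConfig(seed = 3, nRecords = 257))
  desc <- compressDataset(h, "fq", fq, parseFastq,
                          fastqJob(chunkRecords = 50))
  counts <- genarc:::.chunkRecordCounts(desc)
  expect_identical(sum(counts), 257L)
  expect_identical(length(counts), nrow(desc@streams[[1]]$chunks))
  expect_identical(counts, c(rep(50L, 5), 7L))
})

test_that("unsorted input with a key function fails at the first inversion", {
  h <- testContainer()
  gc0 <- generatorConfig(seed = 5, nRecords = 60, sorted = FALSE,
                         fracUnmapped = 0)
  sam <- generateSam(generateReference(gc0), gc0)
  refOrder <- samHeaderRefs(parseSam(sam)$header)
  job <- samJob(sorted = TRUE, referenceOrder = refOrder, chunkRecords = 20)
  err <- tryCatch(compressDataset(h, "s", sam, parseSam, job),
                  genarcDataError = identity)
  expect_match(conditionMessage(err), "not sorted")
  expect_match(conditionMessage(err), "record [0-9]+")
  # the first inversion specifically
  keys <- lapply(parseSam(sam)$records, samKeyFun(refOrder))
  firstBad <- which(vapply(seq_len(length(keys) - 1), function(i)
    compareKeys(keys[[i]], keys[[i + 1]]) > 0, TRUE))[1] + 1L
  expect_match(conditionMessage(err),
               sprintf("record %d", firstBad), fixed = TRUE)
  # and nothing entered the catalog, no blocks leaked
  expect_length(listDatasets(h), 0L)
  expect_true(all(blockStates(h) != 1L))
})

test_that("container bytes do not depend on the worker count", {
  fq <- generateFastq(generatorConfig(seed = 6, nRecords = 600))
  datafile <- function(workers) {
    p <- tmpPrefix()
    h <- createContainer(p, containerConfig(65536, 4096, 8, 64))
    compressDataset(h, "fq", fq, parseFastq,
                    fastqJob(chunkRecords = 100, workers = workers))
    closeContainer(h)
    readBin(paste0(p, ".genarc-data"), raw(),
            file.size(paste0(p, ".genarc-data")))
  }
  expect_identical(datafile(1), datafile(4))
})

test_that("key samples record the first key of every chunk", {
  h <- testContainer()
  gc0 <- generatorConfig(seed = 8, nRecords = 120, fracUnmapped = 0)
  sam <- generateSam(generateReference(gc0), gc0)
  refOrder <- samHeaderRefs(parseSam(sam)$header)
  desc <- compressDataset(h, "s", sam, parseSam,
                          samJob(sorted = TRUE, referenceOrder = refOrder,
                                 chunkRecords = 25))
  ks <- keySamples(desc)
  expect_length(ks, 5L)
  recs <- parseSam(sam)$records
  for (ci in seq_along(ks))
    expect_identical(compareKeys(ks[[ci]],
                                 samPositionKey(recs[[(ci - 1) * 25 + 1]],
                                                refOrder)), 0L)
})

test_that("bisection agrees with a linear-scan oracle and stays minimal", {
  set.seed(777)
  for (rep in 1:4) {
    nChunks <- sample(c(1, 3, 17, 64), 1)
    per <- 20L
    # sorted synthetic record keys over a 2-contig keyspace, chunked
    recKeys <- sort(sample(0:5000, nChunks * per, replace = TRUE))
    chunkOf <- rep(seq_len(nChunks), each = per)
    samples <- lapply(seq_len(nChunks), function(ci)
      .k2(recKeys[which(chunkOf == ci)[1]]))
    for (q in 1:250) {
      ab <- sort(sample(0:5200, 2, replace = TRUE))
      lo <- .k2(ab[1]); hi <- .k2(ab[2])
      loc <- genarc:::.locateBisect(samples, lo, hi)
      # oracle: chunks actually holding a record with key in [lo, hi]
      match_ <- recKeys >= ab[1] & recKeys <= ab[2]
      inside <- unique(chunkOf[match_])
      got <- if (loc["lastExcl"] > loc["first"])
        seq.int(loc["first"] + 1, loc["lastExcl"]) else integer(0)
      expect_true(all(inside %in% got))
      expect_lte(length(got), length(inside) + 2L)
    }
  }
})

test_that("bisection comparison counts stay within the logarithmic bound", {
  set.seed(31)
  for (nChunks in c(1, 2, 64, 1024)) {
    keys <- sort(sample(0:10^6, nChunks, replace = TRUE))
    samples <- lapply(keys, function(k) list(k))
    bound <- 2 * ceiling(log2(max(nChunks, 1))) + 2
    worst <- 0L
    for (q in 1:100) {
      ab <- sort(sample(0:10^6, 2, replace = TRUE))
      loc <- genarc:::.locateBisect(samples, list(ab[1]), list(ab[2]))
      worst <- max(worst, attr(loc, "comparisons"))
    }
    expect_lte(worst, bound)
  }
})

test_that("range queries equal a brute-force filter over a full decompress", {
  h <- testContainer()
  gc0 <- generatorConfig(seed = 12, nRecords = 3000, nContigs = 3,
                         contigLength = 40000)
  sam <- generateSam(generateReference(gc0), gc0)
  refOrder <- samHeaderRefs(parseSam(sam)$header)
  desc <- compressDataset(h, "s", sam, parseSam,
                          samJob(sorted = TRUE, referenceOrder = refOrder,
                                 chunkRecords = 250))
  recs <- parseSam(sam)$records
  keys <- lapply(recs, samKeyFun(refOrder))
  set.seed(13)
  for (q in 1:30) {
    ctg <- sample(0:2, 1)
    ab <- sort(sample(0:41000, 2, replace = TRUE))
    lo <- list(ctg, ab[1]); hi <- list(ctg, ab[2])
    got <- queryRange(h, "s", lo, hi, samKeyFun(refOrder))
    want <- recs[vapply(keys, function(k)
      compareKeys(lo, k) <= 0 && compareKeys(k, hi) <= 0, TRUE)]
    attributes(got) <- NULL
    expect_equal(got, want)
  }
  # a full-range query equals the full decompression
  full <- queryRange(h, "s", list(0, 0), list(10, 2^31),
                     samKeyFun(refOrder), unparser = unparseSamRecords)
  expect_identical(paste0(getDataset(h, "s")@headerText, full),
                   decompressDataset(h, "s", unparseSamRecords))
})

test_that("queries on an unsorted dataset are refused", {
  h <- testContainer()
  gc0 <- generatorConfig(seed = 14, nRecords = 40, sorted = FALSE)
  sam <- generateSam(generateReference(gc0), gc0)
  compressDataset(h, "s", sam, parseSam, samJob(sorted = FALSE,
                                                chunkRecords = 20))
  expect_error(queryRange(h, "s", list(0, 1), list(0, 2),
                          samKeyFun(character(0))),
               class = "genarcDataError")
})

test_that("an empty key intersection returns no records", {
  h <- testContainer()
  gc0 <- generatorConfig(seed = 15, nRecords = 50, fracUnmapped = 0,
                         nContigs = 1)
  sam <- generateSam(generateReference(gc0), gc0)
  refOrder <- samHeaderRefs(parseSam(sam)$header)
  compressDataset(h, "s", sam, parseSam,
                  samJob(sorted = TRUE, referenceOrder = refOrder,
                         chunkRecords = 10))
  res <- queryRange(h, "s", list(5, 0), list(5, 10), samKeyFun(refOrder))
  expect_length(res, 0L)
})
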