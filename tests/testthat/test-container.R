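# Container layer: creation, allocation, block I/O, catalog, verify, shrink.

test_that("creation pre-sizes the data area from the geometry", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(65536, 4096, 4, 4))
  on.exit(closeContainer(h))
  expect_identical(file.size(paste0(p, ".genarc-data")),
                   4 * 65536 + 4 * 4096)  # 278528
  expect_length(listDatasets(h), 0L)
  expect_true(all(blockStates(h) == 0L))
  expect_error(createContainer(p, containerConfig(65536, 4096, 4, 4)),
               class = "genarcUsageError")
})

test_that("a zero-block container is valid but cannot allocate", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(65536, 4096, 0, 0))
  on.exit(closeContainer(h))
  expect_identical(file.size(paste0(p, ".genarc-data")), 0)
  expect_error(allocate(h, 1), class = "genarcDataError")
  expect_identical(allocate(h, 0), numeric(0))
})

test_that("reopening a container restores geometry, states and catalog", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(65536, 4096, 4, 4))
  b <- allocate(h, 1000)
  writeStreamBytes(h, b, as.raw(rep_len(1:250, 1000)))
  closeContainer(h)
  h2 <- openContainer(p)
  expect_identical(containerGeometry(h2)@bigBlockSize, 65536)
  expect_identical(sum(blockStates(h2) == 2L), length(b))
  expect_length(listDatasets(h2), 0L)
})

test_that("allocation is greedy: full big blocks, then minimal small tail", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(65536, 4096, 8, 8))
  on.exit(closeContainer(h))
  # capacities: big 65528, small 4088; 70000 = 65528 + 4472 -> 2 smalls
  b <- allocate(h, 70000)
  expect_identical(b, c(0, 8, 9))
  releaseBlocks(h, b)
  # tail that exactly fits one small block
  b2 <- allocate(h, 65528 + 4088)
  expect_identical(b2, c(0, 8))
  releaseBlocks(h, b2)
  # tail too big for the free smalls -> one more big block
  invisible(allocate(h, 7 * 4088))         # consume 7 smalls
  b3 <- allocate(h, 65528 + 4472)          # needs 2 smalls, 1 free -> big
  expect_identical(b3, c(0, 1))
})

test_that("failed allocation leaves the allocation table unchanged", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(65536, 4096, 2, 2))
  on.exit(closeContainer(h))
  before <- blockStates(h)
  expect_error(allocate(h, 10 * 65536), class = "genarcDataError")
  expect_identical(blockStates(h), before)
  total <- sum(blockStates(h) == 0L) + sum(blockStates(h) == 1L) +
    sum(blockStates(h) == 2L)
  expect_identical(total, 4L)
})

test_that("write/read round-trips bytes across block boundaries", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(4096, 512, 4, 8))
  on.exit(closeContainer(h))
  set.seed(31)
  data <- as.raw(sample(0:255, 9000, replace = TRUE))  # 2 big + small tail
  b <- allocate(h, length(data))
  expect_gt(length(b), 2L)
  writeStreamBytes(h, b, data)
  desc <- new("DatasetDescriptor", name = "d", schemaText = "",
              headerText = "", nRecords = 0, chunkRecords = 1,
              streams = list(list(path = "s", method = "raw",
                                  level = 0, blocks = b,
                                  totalBytes = length(data),
                                  chunks = matrix(c(0, length(data),
                                                    length(data)), 1,
                                                  dimnames = list(NULL,
                                                    c("offset", "clen",
                                                      "ulen"))))),
              keySamples = NULL)
  expect_identical(readStreamBytes(h, desc, "s", 0, length(data)), data)
  # a slice spanning the first big/second block boundary
  expect_identical(readStreamBytes(h, desc, "s", 4000, 400),
                   data[4001:4400])
  expect_error(readStreamBytes(h, desc, "s", 8990, 100),
               class = "genarcUsageError")
})

test_that("writing to a non-reserved block is rejected", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(4096, 512, 2, 2))
  on.exit(closeContainer(h))
  expect_error(writeStreamBytes(h, 0, as.raw(1:10)),
               class = "genarcUsageError")
  b <- allocate(h, 10)
  expect_error(writeStreamBytes(h, b, as.raw(rep(7L, 5000))),
               class = "genarcDataError")  # capacity overflow
})

test_that("block checksums agree with an independent CRC32 implementation", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(4096, 512, 1, 1))
  on.exit(closeContainer(h))
  set.seed(8)
  data <- as.raw(sample(0:255, 600, replace = TRUE))
  b <- allocate(h, length(data))
  writeStreamBytes(h, b, data)
  cfg <- containerGeometry(h)
  con <- file(paste0(p, ".genarc-data"), "rb")
  on.exit(close(con), add = TRUE)
  fills <- genarc:::.payloadLens(cfg, b, length(data))
  for (i in seq_along(b)) {
    off <- genarc:::.blockOffset(cfg, b[i])
    seek(con, off + genarc:::.blockSize(cfg, b[i]) - 8)
    trailer <- readBin(con, raw(), 8)
    seek(con, off)
    payload <- readBin(con, raw(), fills[i])
    expect_identical(genarc:::.unpackFixed(trailer[5:8], 4),
                     crc32Oracle(payload))
  }
})

test_that("the catalog round-trips descriptors exactly", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(4096, 512, 4, 4))
  b <- allocate(h, 100)
  writeStreamBytes(h, b, as.raw(1:100))
  desc <- new("DatasetDescriptor", name = "ds1",
              schemaText = "@record R {\n  x: u32;\n}\n",
              headerText = "@HD\tVN:1.6\n", nRecords = 25, chunkRecords = 10,
              streams = list(list(path = "x", method = "gzip", level = 6,
                                  blocks = b, totalBytes = 100,
                                  chunks = matrix(c(0, 40, 60, 40, 20, 40,
                                                    100, 60, 80), 3,
                                                  dimnames = list(NULL,
                                                    c("offset", "clen",
                                                      "ulen"))))),
              keySamples = list(list(0, 1), list(0, 500), list(1, 2)))
  addDataset(h, desc)
  expect_error(addDataset(h, desc), class = "genarcUsageError")
  expect_error(getDataset(h, "nope"), class = "genarcUsageError")
  closeContainer(h)
  h2 <- openContainer(p)
  d2 <- getDataset(h2, "ds1")
  expect_identical(d2@schemaText, desc@schemaText)
  expect_identical(d2@headerText, desc@headerText)
  expect_identical(d2@nRecords, desc@nRecords)
  expect_identical(d2@streams[[1]]$chunks, desc@streams[[1]]$chunks)
  expect_identical(d2@streams[[1]]$blocks, as.numeric(b))
  expect_identical(d2@keySamples, desc@keySamples)
})

test_that("two interleaved datasets decode independently", {
  h <- testContainer(big = 4096, small = 512, nBig = 8, nSmall = 32)
  fq1 <- generateFastq(generatorConfig(seed = 21, nRecords = 80,
                                       readLength = c(50, 60)))
  fq2 <- generateFastq(generatorConfig(seed = 22, nRecords = 90,
                                       readLength = c(30, 40)))
  # alternate block reservations by compressing into the same container
  compressDataset(h, "a", fq1, parseFastq, fastqJob(chunkRecords = 25))
  compressDataset(h, "b", fq2, parseFastq, fastqJob(chunkRecords = 30))
  expect_identical(decompressDataset(h, "a", unparseFastqRecords), fq1)
  expect_identical(decompressDataset(h, "b", unparseFastqRecords), fq2)
  # no block is referenced by two streams
  refs <- unlist(lapply(listDatasets(h), function(nm)
    lapply(getDataset(h, nm)@streams, function(s) s$blocks)))
  expect_false(anyDuplicated(refs) > 0)
  # every occupied block is referenced exactly once
  expect_setequal(refs, which(blockStates(h) == 2L) - 1)
})

test_that("verify is clean on a pristine container and names corrupt blocks", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(4096, 512, 8, 16))
  fq <- generateFastq(generatorConfig(seed = 23, nRecords = 60))
  compressDataset(h, "fq", fq, parseFastq, fastqJob(chunkRecords = 30))
  expect_identical(nrow(verifyContainer(h)), 0L)
  # flip one payload byte inside an occupied block
  desc <- getDataset(h, "fq")
  blk <- desc@streams[[2]]$blocks[1]
  off <- genarc:::.blockOffset(containerGeometry(h), blk)
  corruptFile(paste0(p, ".genarc-data"), off + 3, 0x40)
  rep <- verifyContainer(h)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$blockId, blk)
  expect_identical(rep$dataset, "fq")
  expect_identical(rep$stream, desc@streams[[2]]$path)
  # the read path refuses the corrupt block too
  expect_error(decompressDataset(h, "fq", unparseFastqRecords),
               class = "genarcIntegrityError")
  # corruption in a free block goes unreported
  corruptFile(paste0(p, ".genarc-data"), off, 0x40)  # restore not needed:
  closeContainer(h)
})

test_that("corruption in a free block is not reported", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(4096, 512, 2, 2))
  on.exit(closeContainer(h))
  b <- allocate(h, 100)
  writeStreamBytes(h, b, as.raw(1:100))
  # last small block is free; flip a byte in it
  freeBlk <- max(which(blockStates(h) == 0L)) - 1
  corruptFile(paste0(p, ".genarc-data"),
              genarc:::.blockOffset(containerGeometry(h), freeBlk) + 5, 0xFF)
  expect_identical(nrow(verifyContainer(h)), 0L)
})

test_that("shrink keeps datasets byte-identical and minimizes the data file", {
  h <- testContainer(big = 8192, small = 1024, nBig = 10, nSmall = 40)
  fq <- generateFastq(generatorConfig(seed = 27, nRecords = 120))
  compressDataset(h, "fq", fq, parseFastq, fastqJob(chunkRecords = 50))
  occBig <- sum(blockStates(h)[1:10] == 2L)
  occSmall <- sum(blockStates(h)[-(1:10)] == 2L)
  out <- tmpPrefix()
  cfg2 <- shrinkContainer(h, out)
  expect_identical(cfg2@nBig, as.numeric(occBig))
  expect_identical(cfg2@nSmall, as.numeric(occSmall))
  expect_identical(file.size(paste0(out, ".genarc-data")),
                   occBig * 8192 + occSmall * 1024)
  h2 <- openContainer(out)
  expect_identical(decompressDataset(h2, "fq", unparseFastqRecords), fq)
  expect_identical(nrow(verifyContainer(h2)), 0L)
})

test_that("an empty container shrinks to zero blocks", {
  h <- testContainer(big = 4096, small = 512, nBig = 2, nSmall = 2)
  out <- tmpPrefix()
  cfg2 <- shrinkContainer(h, out)
  expect_identical(cfg2@nBig + cfg2@nSmall, 0)
  expect_identical(file.size(paste0(out, ".genarc-data")), 0)
})

test_that("shrink refuses containers with reserved blocks", {
  h <- testContainer(big = 4096, small = 512, nBig = 2, nSmall = 2)
  allocate(h, 100)
  expect_error(shrinkContainer(h, tmpPrefix()), class = "genarcUsageError")
})

test_that("allocation states always sum to the block count (randomized ops)", {
  set.seed(404)
  h <- testContainer(big = 4096, small = 512, nBig = 6, nSmall = 12)
  total <- 18L
  reserved <- list()
  checkConservation <- function() {
    st <- blockStates(h)
    expect_identical(sum(st == 0L) + sum(st == 1L) + sum(st == 2L), total)
  }
  for (i in 1:60) {
    op <- sample(c("alloc", "write", "release"), 1)
    if (op == "alloc") {
      n <- sample(1:6000, 1)
      res <- tryCatch(allocate(h, n), genarcDataError = function(e) NULL)
      if (!is.null(res) && length(res))
        reserved[[length(reserved) + 1]] <- res
    } else if (length(reserved)) {
      b <- reserved[[1]]
      reserved <- reserved[-1]
      if (op == "write")
        writeStreamBytes(h, b, as.raw(rep(7, sum(
          genarc:::.blockCapacity(containerGeometry(h), b)))))
      else releaseBlocks(h, b)
    }
    checkConservation()
    # reserved count matches what we still hold
    expect_identical(sum(blockStates(h) == 1L),
                     length(unlist(reserved)))
  }
})

test_that("the writer lock excludes a second writer but not readers", {
  p <- tmpPrefix()
  h <- createContainer(p, containerConfig(4096, 512, 2, 2))
  allocate(h, 10)      # takes the lock
  h2 <- openContainer(p)
  expect_error(allocate(h2, 10), class = "genarcUsageError")
  expect_length(listDatasets(h2), 0L)   # reading is fine
  closeContainer(h)
  expect_silent(allocate(h2, 10))
  closeContainer(h2)
})
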