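# Little-endian fixed-width packing shared by the stream serializer and the
# container's meta file.  Values are carried as doubles; 8-byte integers are
# exact for |value| < 2^53, which covers every offset and count this package
# can produce.

.packFixed <- function(x, width, signed = FALSE, path = "<value>",
                       ords = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(raw(0))
  lim <- 2^(8 * width)
  lo <- if (signed) -lim / 2 else 0
  hi <- if (signed) lim / 2 else lim
  bad <- which(!is.finite(x) | x < lo | x >= hi | x != trunc(x))
  if (length(bad)) {
    ord <- if (is.null(ords)) bad[1] else ords[bad[1]]
    stopData("value %s out of range for %d-byte %s field at '%s' (record %d)",
             format(x[bad[1]]), width, if (signed) "signed" else "unsigned",
             path, ord)
  }
  xx <- x + (x < 0) * lim
  out <- raw(n * width)
  for (i in seq_len(width)) {
    byte <- xx %% 256
    out[seq.int(i, by = width, length.out = n)] <- as.raw(byte)
    xx <- (xx - byte) / 256
  }
  out
}

.unpackFixed <- function(r, width, signed = FALSE) {
  if (length(r) == 0L) return(numeric(0))
  m <- matrix(as.numeric(r), nrow = width)
  x <- as.numeric(256^(0:(width - 1)) %*% m)
  if (signed) {
    half <- 2^(8 * width - 1)
    x <- x - (x >= half) * 2^(8 * width)
  }
  x
}

# integer-exact decimal formatting (avoids scientific notation on doubles)
.fmtInt <- function(x) formatC(x, format = "d")

.crc32 <- function(data) .Call(C_crc32, data)

# splitmix64 deviates in [0, 1); the only randomness source of the fixture
# generators.
.rngUniform <- function(seed, n) .Call(C_rng_uniform, as.numeric(seed),
                                       as.numeric(n))
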