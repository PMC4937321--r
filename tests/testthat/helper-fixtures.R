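# Shared helpers: scratch containers, random schema/record generators.

tmpPrefix <- function() tempfile("genarc-test-")

# a container comfortably sized for small end-to-end tests
testContainer <- function(big = 262144, small = 4096, nBig = 16,
                          nSmall = 256) {
  h <- createContainer(tmpPrefix(), containerConfig(big, small, nBig, nSmall))
  withr::defer(closeContainer(h), envir = parent.frame())
  h
}

# ---------------------------------------------------------------------------
# random schema documents (for parse/render round-trip properties)
# ---------------------------------------------------------------------------

randName <- function() {
  paste0(sample(letters, 1), paste(sample(c(letters, "_", 0:9), sample(0:6, 1),
                                          replace = TRUE), collapse = ""))
}

randCodec <- function() {
  if (runif(1) < 0.4) return(NULL)
  m <- sample(c("raw", "gzip", "bzip2", "lzma"), 1)
  lv <- if (runif(1) < 0.5) NA_real_ else
    round(runif(1, codecLevelRange(m)[1], codecLevelRange(m)[2]))
  codecSpec(m, lv)
}

randType <- function(depth, defNames = character(0)) {
  choices <- c("prim", "prim", "prim")
  if (depth > 0) choices <- c(choices, "fixed", "var", "record", "union")
  if (length(defNames)) choices <- c(choices, "ref")
  switch(sample(choices, 1),
         prim = primitiveType(sample(genarc:::.PRIMITIVE_KINDS, 1)),
         ref = namedRefType(sample(defNames, 1)),
         fixed = fixedArrayType(randType(depth - 1, defNames),
                                sample(1:4, 1)),
         var = varArrayType(randType(depth - 1, defNames)),
         record = recordType(randFields(depth - 1, defNames,
                                        sample(1:3, 1))),
         union = unionType(randFields(depth - 1, defNames,
                                      sample(2:3, 1))))
}

randFields <- function(depth, defNames, n) {
  nms <- character(0)
  while (length(nms) < n) nms <- unique(c(nms, randName()))
  lapply(nms[seq_len(n)], function(nm)
    fieldDef(nm, randType(depth, defNames), randCodec()))
}

randSchemaDoc <- function() {
  nDefs <- sample(0:2, 1)
  defs <- list()
  for (i in seq_len(nDefs)) {
    nm <- randName()
    while (nm %in% names(defs)) nm <- randName()
    defs[[nm]] <- randType(1, names(defs))
  }
  entryName <- randName()
  while (entryName %in% names(defs)) entryName <- randName()
  schemaDoc(defs, entryName,
            recordType(randFields(2, names(defs), sample(1:4, 1))))
}

# ---------------------------------------------------------------------------
# random record values conforming to a resolved schema
# ---------------------------------------------------------------------------

randString <- function(maxLen = 8, alphabet = c(LETTERS, letters, 0:9)) {
  paste(sample(alphabet, sample(0:maxLen, 1), replace = TRUE), collapse = "")
}

randPrimValue <- function(kind) {
  switch(kind,
         u8 = sample(0:255, 1), u16 = sample(0:65535, 1),
         u32 = floor(runif(1, 0, 2^32)), u64 = floor(runif(1, 0, 2^50)),
         i32 = floor(runif(1, -2^31, 2^31)),
         i64 = floor(runif(1, -2^50, 2^50)),
         char = rawToChar(as.raw(sample(33:126, 1))),
         flag = runif(1) < 0.5,
         string = randString(),
         dna = randString(12, c("A", "C", "G", "T", "N")),
         qual = randString(12, strsplit(rawToChar(as.raw(33:74)), "")[[1]]))
}

randValue <- function(type) {
  if (is(type, "PrimitiveType")) return(randPrimValue(type@kind))
  if (is(type, "FixedArrayType")) {
    vals <- lapply(seq_len(type@length), function(i) randValue(type@element))
    if (is(type@element, "PrimitiveType") &&
        !type@element@kind %in% c("string", "dna", "qual", "char"))
      return(unlist(vals))
    if (is(type@element, "PrimitiveType")) return(unlist(vals))
    return(vals)
  }
  if (is(type, "VarArrayType")) {
    n <- sample(0:4, 1)
    vals <- lapply(seq_len(n), function(i) randValue(type@element))
    if (is(type@element, "PrimitiveType")) {
      flat <- unlist(vals)
      return(if (is.null(flat)) .emptyPrim(type@element@kind) else flat)
    }
    return(vals)
  }
  if (is(type, "RecordType")) {
    out <- lapply(type@fields, function(f) randValue(f@type))
    names(out) <- vapply(type@fields, function(f) f@name, "")
    return(out)
  }
  if (is(type, "UnionType")) {
    i <- sample(seq_along(type@alternatives), 1)
    return(list(alt = i, value = randValue(type@alternatives[[i]]@type)))
  }
  stop("unexpected node")
}

.emptyPrim <- function(kind)
  if (kind %in% c("string", "dna", "qual", "char")) character(0) else numeric(0)

randRecords <- function(schema, n)
  lapply(seq_len(n), function(i) randValue(schema@root))

# independent CRC32 implementation (table-driven, reflected 0xEDB88320),
# used as an oracle against the package's checksum.  32-bit xor is done on
# doubles split into 16-bit halves so it stays exact in base R.
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

crc32Oracle <- local({
  tab <- NULL
  function(data) {
    if (is.null(tab)) {
      t <- numeric(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8)
          c <- if (c %% 2) xor32(0xEDB88320, c %/% 2) else c %/% 2
        t[i + 1] <- c
      }
      tab <<- t
    }
    crc <- 0xFFFFFFFF
    for (b in as.integer(data)) {
      idx <- bitwXor(as.integer(crc %% 256), b)
      crc <- xor32(tab[idx + 1], crc %/% 256)
    }
    xor32(crc, 0xFFFFFFFF)
  }
})
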