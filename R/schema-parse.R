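# Parser for the record-definition meta-language.
#
# Grammar (documented in docs/FORMAT.md and the methods vignette):
#
#   document  := { definition } ;  exactly one "@record" definition
#   definition:= name "=" type ";"
#              | "@record" name record-body [";"]
#   record-body := "{" { field } "}"
#   field     := name ":" type [ "@" method [ "(" level ")" ] ] ";"
#   type      := base { "[" [ integer ] "]" }
#   base      := primitive | name | record-body
#              | "union" "{" field field { field } "}"
#   primitive := u8|u16|u32|u64|i32|i64|char|flag|string|dna|qual
#
# "#" starts a comment running to end of line; whitespace is insignificant.
# Array suffixes apply left to right: "u32[3][]" is a variable-length array
# of fixed triples.

.TOKEN_RE <- "^([A-Za-z_][A-Za-z0-9_]*|[0-9]+|[@=;:{}\\[\\]()])"

.tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- vector("list", 256L)
  k <- 0L
  for (ln in seq_along(lines)) {
    s <- sub("#.*$", "", lines[[ln]])
    n <- nchar(s)
    pos <- 1L
    while (pos <= n) {
      ch <- substr(s, pos, pos)
      if (ch %in% c(" ", "\t", "\r")) { pos <- pos + 1L; next }
      m <- regexpr(.TOKEN_RE, substr(s, pos, n), perl = TRUE)
      if (m == -1L)
        stopSchema(ln, pos, "unexpected character '%s'", ch)
      len <- attr(m, "match.length")
      tk <- substr(s, pos, pos + len - 1L)
      k <- k + 1L
      if (k > length(toks)) toks <- c(toks, vector("list", length(toks)))
      toks[[k]] <- list(
        text = tk,
        type = if (grepl("^[0-9]", tk)) "int"
               else if (grepl("^[A-Za-z_]", tk)) "ident" else tk,
        line = ln, col = pos)
      pos <- pos + len
    }
  }
  toks[seq_len(k)]
}

# parser cursor over the token list
.newCursor <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env$lastLine <- if (length(toks)) toks[[length(toks)]]$line else 1L
  env
}

.peek <- function(cur) {
  if (cur$i > length(cur$toks)) NULL else cur$toks[[cur$i]]
}

.advance <- function(cur) {
  t <- .peek(cur)
  cur$i <- cur$i + 1L
  t
}

.errHere <- function(cur, fmt, ...) {
  t <- .peek(cur)
  if (is.null(t))
    stopSchema(cur$lastLine, 1L, "unexpected end of input: %s",
               sprintf(fmt, ...))
  stopSchema(t$line, t$col, "%s, found '%s'", sprintf(fmt, ...), t$text)
}

.expect <- function(cur, type, what = sprintf("expected '%s'", type)) {
  t <- .peek(cur)
  if (is.null(t) || t$type != type) .errHere(cur, what)
  .advance(cur)
}

.expectIdent <- function(cur, what = "expected identifier")
  .expect(cur, "ident", what)

#' Parse a schema document
#'
#' Parses meta-language source into a [SchemaDoc-class]: an ordered list of
#' named type definitions plus exactly one entry record marked `@record`.
#' Source line/column are attached to every node.  No name resolution is
#' performed; see [resolveTypes()].
#'
#' @param text schema source (single string, UTF-8).
#' @return a [SchemaDoc-class].
#' @examples
#' doc <- parseSchema(
#'   "@record Fastq { name: string @gzip; seq: dna @bzip2; qual: qual @bzip2; }")
#' doc
#' @seealso [renderSchema()], [resolveTypes()]
#' @export
parseSchema <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  cur <- .newCursor(.tokenize(text))
  defs <- list()
  entry <- NULL
  entryName <- NULL
  while (!is.null(t <- .peek(cur))) {
    if (t$type == "@") {
      .advance(cur)
      kw <- .expectIdent(cur, "expected 'record' after '@'")
      if (kw$text != "record")
        stopSchema(kw$line, kw$col, "unknown directive '@%s'", kw$text)
      nm <- .expectIdent(cur, "expected record name")
      if (nm$text %in% names(defs) || identical(nm$text, entryName))
        stopSchema(nm$line, nm$col, "duplicate type name '%s'", nm$text)
      if (!is.null(entry))
        stopSchema(nm$line, nm$col,
                   "multiple @record directives (entry is already '%s')",
                   entryName)
      entry <- .parseRecordBody(cur, nm$line, nm$col)
      entryName <- nm$text
      if (!is.null(p <- .peek(cur)) && p$type == ";") .advance(cur)
    } else if (t$type == "ident") {
      nm <- .advance(cur)
      if (nm$text %in% names(defs) || identical(nm$text, entryName))
        stopSchema(nm$line, nm$col, "duplicate type name '%s'", nm$text)
      .expect(cur, "=", "expected '=' in type definition")
      ty <- .parseType(cur)
      .expect(cur, ";", "expected ';' after type definition")
      defs[[nm$text]] <- ty
    } else {
      .errHere(cur, "expected type definition or '@record'")
    }
  }
  if (is.null(entry)) {
    ln <- cur$lastLine
    stopSchema(ln, 1L, "no @record directive: the entry record is missing")
  }
  schemaDoc(defs = defs, entryName = entryName, entry = entry)
}

.parseRecordBody <- function(cur, line, col) {
  .expect(cur, "{", "expected '{' to open record body")
  fields <- list()
  nms <- character()
  repeat {
    t <- .peek(cur)
    if (is.null(t)) .errHere(cur, "expected field or '}'")
    if (t$type == "}") { .advance(cur); break }
    f <- .parseField(cur)
    if (f@name %in% nms)
      stopSchema(f@srcLine, f@srcCol, "duplicate field name '%s'", f@name)
    nms <- c(nms, f@name)
    fields <- c(fields, list(f))
  }
  node <- recordType(fields)
  node@srcLine <- line; node@srcCol <- col
  node
}

.parseField <- function(cur) {
  nm <- .expectIdent(cur, "expected field name")
  .expect(cur, ":", "expected ':' after field name")
  ty <- .parseType(cur)
  codec <- NULL
  if (!is.null(p <- .peek(cur)) && p$type == "@") {
    .advance(cur)
    mth <- .expectIdent(cur, "expected codec method after '@'")
    level <- NA_real_
    if (!is.null(q <- .peek(cur)) && q$type == "(") {
      .advance(cur)
      lv <- .expect(cur, "int", "expected integer codec level")
      level <- as.numeric(lv$text)
      .expect(cur, ")", "expected ')' after codec level")
    }
    codec <- codecSpec(mth$text, level)
  }
  .expect(cur, ";", "expected ';' after field")
  f <- fieldDef(nm$text, ty, codec)
  f@srcLine <- nm$line; f@srcCol <- nm$col
  f
}

.parseType <- function(cur) {
  t <- .peek(cur)
  if (is.null(t)) .errHere(cur, "expected type")
  if (t$type == "ident" && t$text == "union") {
    .advance(cur)
    .expect(cur, "{", "expected '{' to open union")
    alts <- list()
    nms <- character()
    repeat {
      p <- .peek(cur)
      if (is.null(p)) .errHere(cur, "expected union alternative or '}'")
      if (p$type == "}") { .advance(cur); break }
      a <- .parseField(cur)
      if (a@name %in% nms)
        stopSchema(a@srcLine, a@srcCol,
                   "duplicate union alternative '%s'", a@name)
      nms <- c(nms, a@name)
      alts <- c(alts, list(a))
    }
    if (length(alts) < 2L)
      stopSchema(t$line, t$col, "union needs at least 2 alternatives")
    base <- unionType(alts)
    base@srcLine <- t$line; base@srcCol <- t$col
  } else if (t$type == "{") {
    base <- .parseRecordBody(cur, t$line, t$col)
  } else if (t$type == "ident") {
    .advance(cur)
    if (t$text %in% .PRIMITIVE_KINDS) {
      base <- primitiveType(t$text)
    } else {
      base <- namedRefType(t$text)
    }
    base@srcLine <- t$line; base@srcCol <- t$col
  } else {
    .errHere(cur, "expected type")
  }
  # array suffixes, applied left to right
  while (!is.null(p <- .peek(cur)) && p$type == "[") {
    .advance(cur)
    q <- .peek(cur)
    if (!is.null(q) && q$type == "int") {
      .advance(cur)
      len <- as.numeric(q$text)
      if (len < 1)
        stopSchema(q$line, q$col, "fixed array length must be >= 1")
      .expect(cur, "]", "expected ']'")
      base <- fixedArrayType(base, len)
    } else {
      .expect(cur, "]", "expected array length or ']'")
      base <- varArrayType(base)
    }
    base@srcLine <- p$line; base@srcCol <- p$col
  }
  base
}
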