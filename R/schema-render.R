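# Canonical rendering of schema documents.  The canonical text is what gets
# stored in the dataset catalog, so it must be deterministic and must
# re-parse to a structurally identical document (render . parse . render is
# the identity on text).

#' Render a schema document to canonical text
#'
#' Deterministic inverse of [parseSchema()]: `parseSchema(renderSchema(d))`
#' is structurally equal to `d` (source positions excepted), and rendering
#' is idempotent.  Fields without a codec annotation render without an `@`
#' clause; codecs with a default (`NA`) level render without a level.
#'
#' @param doc a [SchemaDoc-class].
#' @return character(1), ending in a newline.
#' @export
renderSchema <- function(doc) {
  stopifnot(is(doc, "SchemaDoc"))
  out <- character(0)
  for (nm in names(doc@defs))
    out <- c(out, sprintf("%s = %s;", nm, .renderType(doc@defs[[nm]], 0L)))
  out <- c(out, sprintf("@record %s %s", doc@entryName,
                        .renderBody(doc@entry, 0L)))
  paste0(paste(out, collapse = "\n"), "\n")
}

.ind <- function(n) strrep("  ", n)

.renderType <- function(t, depth) {
  if (is(t, "PrimitiveType")) return(t@kind)
  if (is(t, "NamedRefType")) return(t@name)
  if (is(t, "FixedArrayType"))
    return(sprintf("%s[%s]", .renderType(t@element, depth),
                   .fmtInt(t@length)))
  if (is(t, "VarArrayType"))
    return(sprintf("%s[]", .renderType(t@element, depth)))
  if (is(t, "RecordType")) return(.renderBody(t, depth))
  if (is(t, "UnionType")) {
    lines <- vapply(t@alternatives, function(a)
      paste0(.ind(depth + 1L), .renderField(a, depth + 1L)), "")
    return(paste0("union {\n", paste(lines, collapse = "\n"),
                  "\n", .ind(depth), "}"))
  }
  stop("unknown type node")  # nocov
}

.renderBody <- function(t, depth) {
  lines <- vapply(t@fields, function(f)
    paste0(.ind(depth + 1L), .renderField(f, depth + 1L)), "")
  paste0("{\n", paste(lines, collapse = "\n"), "\n", .ind(depth), "}")
}

.renderField <- function(f, depth) {
  ann <- if (is.null(f@codec)) "" else
    if (is.na(f@codec@level)) sprintf(" @%s", f@codec@method) else
      sprintf(" @%s(%s)", f@codec@method, .fmtInt(f@codec@level))
  sprintf("%s: %s%s;", f@name, .renderType(f@type, depth), ann)
}
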