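# Name resolution: named references are inlined into the entry record.
# Definitions are ordered and may only reference earlier definitions, which
# makes cycle detection total: the only possible cycle is a definition
# referring to itself (directly or through the definition currently being
# resolved).

#' Resolve a schema document into a record schema
#'
#' Inlines every named reference (definitions are ordered; references to
#' later or unknown definitions are errors, self-references are reported as
#' cycles with their path), validates codec annotations against the codec
#' registry and fills in method-default levels where an annotation gives
#' none.  Fields with no annotation at all inherit the nearest enclosing
#' annotation at stream-planning time ([planStreams()]), falling back to
#' gzip level 6.
#'
#' @param doc a [SchemaDoc-class] from [parseSchema()].
#' @return a [RecordSchema-class].
#' @export
resolveTypes <- function(doc) {
  stopifnot(is(doc, "SchemaDoc"))
  resolved <- list()
  for (nm in names(doc@defs))
    resolved[[nm]] <- .subst(doc@defs[[nm]], resolved, nm)
  root <- .subst(doc@entry, resolved, doc@entryName)
  root <- .defaultLevels(root)
  new("RecordSchema", name = doc@entryName, root = root)
}

.subst <- function(node, resolved, current) {
  if (is(node, "NamedRefType")) {
    if (node@name == current)
      stopSchema(.posLine(node), .posCol(node),
                 "type reference cycle: %s -> %s", current, node@name)
    if (!node@name %in% names(resolved))
      stopSchema(.posLine(node), .posCol(node),
                 "unresolved type name '%s' (definitions are ordered; only earlier definitions can be referenced)",
                 node@name)
    return(resolved[[node@name]])
  }
  if (is(node, "FixedArrayType")) {
    node@element <- .subst(node@element, resolved, current)
    return(node)
  }
  if (is(node, "VarArrayType")) {
    node@element <- .subst(node@element, resolved, current)
    return(node)
  }
  if (is(node, "RecordType")) {
    node@fields <- lapply(node@fields, function(f) {
      f@type <- .subst(f@type, resolved, current)
      f
    })
    return(node)
  }
  if (is(node, "UnionType")) {
    node@alternatives <- lapply(node@alternatives, function(f) {
      f@type <- .subst(f@type, resolved, current)
      f
    })
    return(node)
  }
  node
}

.posLine <- function(node) if (is.na(node@srcLine)) 1L else as.integer(node@srcLine)
.posCol <- function(node) if (is.na(node@srcCol)) 1L else as.integer(node@srcCol)

# validate codec methods and fill in default levels on annotated fields
.defaultLevels <- function(node) {
  fixField <- function(f) {
    if (!is.null(f@codec)) {
      if (!codecRegistered(f@codec@method))
        stopSchema(.posLine(f@type), .posCol(f@type),
                   "field '%s' names unregistered codec '%s'",
                   f@name, f@codec@method)
      entry <- .codecLookup(f@codec@method)
      f@codec@level <- .codecLevel(f@codec, entry)
    }
    f@type <- .defaultLevels(f@type)
    f
  }
  if (is(node, "RecordType")) {
    node@fields <- lapply(node@fields, fixField)
  } else if (is(node, "UnionType")) {
    node@alternatives <- lapply(node@alternatives, fixField)
  } else if (is(node, "FixedArrayType") || is(node, "VarArrayType")) {
    node@element <- .defaultLevels(node@element)
  }
  node
}
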