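# RDF term encoding.
#
# Every RDF term in this package has a single canonical string encoding, the
# N-Triples surface form:
#   URIs      <http://...>
#   literals  "lexical"            (simple literal; RDF 1.1 == xsd:string)
#             "lexical"@en         (language-tagged)
#             "lexical"^^<dtype>   (datatyped)
# Statement tables, variable bindings in the pattern engine and query results
# all carry terms in this form, so term equality is plain string equality and
# set semantics reduce to unique() on character columns.

XSD_STRING <- "http://www.w3.org/2001/XMLSchema#string"
XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"
XSD_FLOAT <- "http://www.w3.org/2001/XMLSchema#float"
XSD_DATETIME <- "http://www.w3.org/2001/XMLSchema#dateTime"

.escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescapeLiteral <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[j]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[i] <- paste0(buf, collapse = "")
  }
  out
}

#' Encode a URI as an RDF term
#'
#' @param uri character vector of absolute URIs (without angle brackets).
#' @return Character vector of encoded terms (\code{"<uri>"}).
#' @export
uriTerm <- function(uri) {
  stopifnot(is.character(uri))
  if (!length(uri)) return(character(0))  # paste0() would yield "<>"
  paste0("<", uri, ">")
}

#' Encode a literal as an RDF term
#'
#' A datatype of \code{xsd:string} is normalised away: in RDF 1.1 a simple
#' literal and an \code{xsd:string}-typed literal denote the same term, and
#' keeping one canonical spelling makes pattern matching exact.  Datatype and
#' language tag are mutually exclusive.
#'
#' @param value character (or coercible) vector of lexical values.
#' @param datatype optional datatype URI, recycled.
#' @param lang optional language tag, recycled.
#' @return Character vector of encoded literal terms.
#' @export
litTerm <- function(value, datatype = NA_character_, lang = NA_character_) {
  value <- as.character(value)
  n <- length(value)
  if (n == 0L) return(character(0))
  datatype <- rep_len(as.character(datatype), n)
  lang <- rep_len(as.character(lang), n)
  if (any(!is.na(datatype) & !is.na(lang)))
    stop("a literal cannot carry both a datatype and a language tag")
  datatype[!is.na(datatype) & datatype == XSD_STRING] <- NA_character_
  core <- paste0("\"", .escapeLiteral(value), "\"")
  out <- core
  hasLang <- !is.na(lang)
  out[hasLang] <- paste0(core[hasLang], "@", lang[hasLang])
  hasDt <- !is.na(datatype)
  out[hasDt] <- paste0(core[hasDt], "^^<", datatype[hasDt], ">")
  out
}

#' Integer / float literal shorthands
#' @param x numeric vector.
#' @return Encoded literal terms.
#' @rdname litTerm
#' @export
intTerm <- function(x) litTerm(format(as.integer(x), scientific = FALSE),
                               datatype = XSD_INTEGER)

#' @rdname litTerm
#' @param digits significant digits used to render float literals.
#' @export
floatTerm <- function(x, digits = 10) {
  lex <- vapply(x, function(v) {
    s <- format(v, digits = digits, scientific = FALSE, trim = TRUE)
    if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
    s
  }, character(1))
  litTerm(lex, datatype = XSD_FLOAT)
}

isURITerm <- function(x) startsWith(x, "<")
isLiteralTerm <- function(x) startsWith(x, "\"")

#' Decode an encoded RDF term
#'
#' @param term a single encoded term.
#' @return List with elements \code{kind} ("uri" or "literal"), \code{value}
#'   (URI string or lexical value), \code{datatype}, \code{lang}.
#' @export
decodeTerm <- function(term) {
  stopifnot(is.character(term), length(term) == 1L)
  if (startsWith(term, "<")) {
    return(list(kind = "uri", value = substr(term, 2L, nchar(term) - 1L),
                datatype = NA_character_, lang = NA_character_))
  }
  if (!startsWith(term, "\""))
    stop("not an encoded RDF term: ", term)
  # find the closing unescaped quote
  m <- regmatches(term, regexec('^"((?:[^"\\\\]|\\\\.)*)"(.*)$', term))[[1]]
  if (length(m) == 0L) stop("malformed literal term: ", term)
  value <- .unescapeLiteral(m[2])
  rest <- m[3]
  datatype <- NA_character_
  lang <- NA_character_
  if (startsWith(rest, "@")) {
    lang <- substring(rest, 2L)
  } else if (startsWith(rest, "^^<")) {
    datatype <- substr(rest, 4L, nchar(rest) - 1L)
    if (datatype == XSD_STRING) datatype <- NA_character_
  } else if (nzchar(rest)) {
    stop("malformed literal term: ", term)
  }
  list(kind = "literal", value = value, datatype = datatype, lang = lang)
}

#' Plain-value view of encoded terms
#'
#' Vectorised: URIs give the URI string, literals their lexical form (this is
#' also the \code{str()} semantics used by query filters).
#'
#' @param terms character vector of encoded RDF terms.
#' @return Character vector of plain values.
#' @export
termValue <- function(terms) {
  out <- terms
  u <- isURITerm(terms)
  out[u] <- substr(terms[u], 2L, nchar(terms[u]) - 1L)
  if (any(!u)) {
    out[!u] <- vapply(terms[!u], function(t) decodeTerm(t)$value, character(1))
  }
  out
}
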