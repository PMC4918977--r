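#' @include triple-graph.R
NULL

# Serialization is deterministic by construction: statements are sorted
# lexicographically on their encoded form, prefixes on their name, so two
# serializations of equal graphs are byte-identical.

.PN_LOCAL_RE <- "^[A-Za-z0-9_][A-Za-z0-9_.-]*$"

# Compact an encoded URI term to a prefixed name where a binding allows it.
.compactURI <- function(enc, ns) {
  uri <- substr(enc, 2L, nchar(enc) - 1L)
  out <- enc
  for (p in names(ns)) {
    base <- ns[[p]]
    hit <- startsWith(uri, base) & out == enc
    if (!any(hit)) next
    local <- substring(uri[hit], nchar(base) + 1L)
    ok <- grepl(.PN_LOCAL_RE, local) & !endsWith(local, ".")
    idx <- which(hit)[ok]
    if (length(idx)) out[idx] <- paste0(p, ":", local[ok])
  }
  out
}

.compactTerm <- function(enc, ns) {
  out <- enc
  u <- isURITerm(enc)
  out[u] <- .compactURI(enc[u], ns)
  # compact datatype URIs inside literals
  lit <- !u & grepl("\\^\\^<", enc)
  if (any(lit)) {
    out[lit] <- vapply(enc[lit], function(t) {
      m <- regmatches(t, regexec('^("(?:[^"\\\\]|\\\\.)*")\\^\\^(<[^>]*>)$', t))[[1]]
      if (length(m) == 0L) return(t)
      paste0(m[2], "^^", .compactURI(m[3], ns))
    }, character(1))
  }
  out
}

#' Serialize a triple graph
#'
#' Output is byte-stable: statements are emitted in lexicographic order.
#' Turtle output uses the graph's namespace bindings to compact URIs to
#' prefixed names; N-Triples output is fully expanded.  Both re-parse to a
#' graph set-equal to the input with any conformant RDF parser.
#'
#' @param graph a \linkS4class{TripleGraph}.
#' @param format \code{"turtle"} or \code{"ntriples"}.
#' @return A single character string (UTF-8 document).
#' @examples
#' g <- tripleGraph("http://identifiers.org/chebi/CHEBI:4167",
#'                  "http://www.w3.org/2000/01/rdf-schema#label",
#'                  litTerm("Glucose", lang = "en"))
#' cat(serializeGraph(g, "ntriples"))
#' @export
serializeGraph <- function(graph, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  stm <- graph@stm[order(.stmKey(graph@stm)), , drop = FALSE]
  if (format == "ntriples") {
    if (nrow(stm) == 0L) return("")
    lines <- paste(stm$subject, stm$predicate, stm$object, ".")
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  ns <- graph@ns[order(names(graph@ns))]
  header <- sprintf("@prefix %s: <%s> .", names(ns), unname(ns))
  lines <- character(0)
  if (nrow(stm)) {
    lines <- paste(.compactTerm(stm$subject, ns), .compactTerm(stm$predicate, ns),
                   .compactTerm(stm$object, ns), ".")
  }
  paste0(paste(c(header, "", lines), collapse = "\n"), "\n")
}

#' Write a graph to a file
#' @inheritParams serializeGraph
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGraph <- function(graph, path, format = c("turtle", "ntriples")) {
  txt <- serializeGraph(graph, format)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

# Scan the RDF terms on one statement line (shared by the N-Triples and
# Turtle readers).  Returns encoded terms; prefixed names are expanded
# against `ns`.
.TERM_RE <- paste0(
  '<[^<>"{}|^`\\\\ ]*>',
  '|"(?:[^"\\\\]|\\\\.)*"(?:@[A-Za-z]+(?:-[A-Za-z0-9]+)*',
  '|\\^\\^(?:<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]+))?',
  '|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.:%#/-]*',
  '|\\ba\\b',
  '|[-+]?[0-9]+(?:\\.[0-9]+)?')

.expandPName <- function(tok, ns) {
  i <- regexpr(":", tok, fixed = TRUE)
  prefix <- substr(tok, 1L, i - 1L)
  local <- substring(tok, i + 1L)
  base <- ns[[prefix]]
  if (is.null(base) || is.na(base))
    stop("undeclared prefix: ", prefix)
  paste0(base, local)
}

.encodeToken <- function(tok, ns) {
  if (startsWith(tok, "<")) return(tok)
  if (startsWith(tok, "\"")) {
    # normalise a prefixed datatype to a full one, and xsd:string away
    m <- regmatches(tok, regexec(
      '^("(?:[^"\\\\]|\\\\.)*")\\^\\^([A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]+)$',
      tok))[[1]]
    if (length(m)) {
      dt <- .expandPName(m[3], ns)
      if (dt == XSD_STRING) return(m[2])
      return(paste0(m[2], "^^<", dt, ">"))
    }
    m <- regmatches(tok, regexec(
      '^("(?:[^"\\\\]|\\\\.)*")\\^\\^<([^>]*)>$', tok))[[1]]
    if (length(m) && m[3] == XSD_STRING) return(m[2])
    return(tok)
  }
  if (tok == "a")
    return(uriTerm("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"))
  if (grepl("^[-+]?[0-9]+$", tok)) return(intTerm(as.integer(tok)))
  if (grepl("^[-+]?[0-9]+\\.[0-9]+$", tok))
    return(litTerm(tok, datatype = XSD_FLOAT))
  uriTerm(.expandPName(tok, ns))
}

.parseStatementLines <- function(lines, ns) {
  lines <- sub("\\s*\\.\\s*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.emptyStatements())
  tokList <- regmatches(lines, gregexpr(.TERM_RE, lines, perl = TRUE))
  bad <- lengths(tokList) != 3L
  if (any(bad))
    stop("cannot parse statement line (expected 3 terms): ",
         lines[bad][1])
  toks <- unlist(tokList, use.names = FALSE)
  enc <- character(length(toks))
  # URIs pass through untouched; everything else through the term encoder
  plain <- startsWith(toks, "<")
  enc[plain] <- toks[plain]
  for (i in which(!plain)) enc[i] <- .encodeToken(toks[i], ns)
  m <- matrix(enc, ncol = 3L, byrow = TRUE)
  data.frame(subject = m[, 1], predicate = m[, 2], object = m[, 3],
             stringsAsFactors = FALSE)
}

#' Read an N-Triples document
#'
#' @param x a file path or a character scalar holding the document.
#' @return A \linkS4class{TripleGraph}.
#' @export
readNTriples <- function(x) {
  lines <- .readDocLines(x)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  graphFromStatements(.parseStatementLines(lines, character(0)))
}

#' Read a Turtle document (line-oriented subset)
#'
#' Reads the Turtle this package writes: \code{@prefix} directives followed
#' by one statement per line (no \code{;}/\code{,} abbreviation).
#'
#' @param x a file path or a character scalar holding the document.
#' @return A \linkS4class{TripleGraph}.
#' @export
readTurtle <- function(x) {
  lines <- .readDocLines(x)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  isPrefix <- grepl("^\\s*@prefix\\s", lines)
  ns <- character(0)
  for (l in lines[isPrefix]) {
    m <- regmatches(l, regexec("@prefix\\s+([A-Za-z][A-Za-z0-9_.-]*):\\s*<([^>]*)>", l))[[1]]
    if (length(m) == 0L) stop("malformed @prefix line: ", l)
    ns[[m[2]]] <- m[3]
  }
  graphFromStatements(.parseStatementLines(lines[!isPrefix], ns),
                      namespaces = if (length(ns)) ns else defaultNamespaces())
}

.readDocLines <- function(x) {
  if (inherits(x, "connection"))
    return(readLines(x, warn = FALSE, encoding = "UTF-8"))
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE, encoding = "UTF-8")
  else
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}
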