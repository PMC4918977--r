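#' @include serialize.R
NULL

# A recursive-descent parser for the SPARQL subset the stock queries and the
# CONSTRUCT rewrite rules use: PREFIX declarations, SELECT (with DISTINCT,
# count aggregates in both the pre-1.1 "count(?x) as ?y" spelling and the
# 1.1 "(COUNT(?x) AS ?y)" one) and CONSTRUCT forms, basic graph patterns
# with ';' and ',' abbreviations, FILTER regex / IN / NOT IN, GROUP BY,
# ORDER BY and LIMIT.  It is not a full SPARQL 1.1 implementation: OPTIONAL,
# UNION, subqueries, paths and SERVICE are out of scope (federated queries
# are shipped as documentation and refused at execution time).

.SPARQL_TOKEN_RE <- paste0(
  "#[^\n]*",                                           # comment
  '|<[^<>"{}|^`\\\\ \n]*>',                            # IRI
  '|"(?:[^"\\\\]|\\\\.)*"',                            # string (suffix below)
  "|\\^\\^",
  "|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",
  "|\\?[A-Za-z_][A-Za-z0-9_]*",                        # variable
  "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.:%#/-]*",      # prefixed name
  "|[A-Za-z][A-Za-z0-9_]*",                            # keyword / 'a' / str
  "|[-+]?[0-9]+(?:\\.[0-9]+)?",
  "|[{}().;,*]")

.tokenizeSPARQL <- function(text) {
  toks <- regmatches(text, gregexpr(.SPARQL_TOKEN_RE, text, perl = TRUE))[[1]]
  toks <- toks[!startsWith(toks, "#")]
  # glue string ^^ datatype / @lang suffixes back onto their literal
  out <- character(0)
  i <- 1L
  while (i <= length(toks)) {
    t <- toks[i]
    if (startsWith(t, "\"") && i < length(toks)) {
      if (toks[i + 1L] == "^^" && i + 2L <= length(toks)) {
        t <- paste0(t, "^^", toks[i + 2L]); i <- i + 2L
      } else if (startsWith(toks[i + 1L], "@")) {
        t <- paste0(t, toks[i + 1L]); i <- i + 1L
      }
    }
    out <- c(out, t)
    i <- i + 1L
  }
  out
}

# cursor over a token vector
.newCursor <- function(tokens) {
  e <- new.env(parent = emptyenv())
  e$toks <- tokens
  e$i <- 1L
  e
}

.peek <- function(cur) if (cur$i <= length(cur$toks)) cur$toks[cur$i] else NA_character_
.advance <- function(cur) { t <- .peek(cur); cur$i <- cur$i + 1L; t }
.expect <- function(cur, tok) {
  t <- .advance(cur)
  if (is.na(t) || tolower(t) != tolower(tok))
    stop(sprintf("query parse error near token %d: expected '%s', got '%s'",
                 cur$i - 1L, tok, t))
  t
}
.isKw <- function(t, kw) !is.na(t) && tolower(t) == tolower(kw)

#' Parse a SPARQL query (subset)
#'
#' @param text query text.
#' @param extraPrefixes named character vector of prefixes available without
#'   declaration (defaults to the well-known set of
#'   \code{\link{defaultNamespaces}}).
#' @return An internal query structure (list) consumed by
#'   \code{\link{runQuery}} and \code{\link{loadRules}}.
#' @keywords internal
parseSPARQL <- function(text, extraPrefixes = defaultNamespaces()) {
  toks <- .tokenizeSPARQL(text)
  cur <- .newCursor(toks)
  ns <- extraPrefixes
  repeat {
    t <- .peek(cur)
    if (!.isKw(t, "PREFIX")) break
    .advance(cur)
    p <- .advance(cur)   # "pfx:" possibly fused with empty local
    iri <- .advance(cur)
    if (!grepl(":$", p) || !startsWith(iri, "<"))
      stop("malformed PREFIX declaration near: ", p)
    ns[[sub(":$", "", p)]] <- substr(iri, 2L, nchar(iri) - 1L)
  }
  form <- toupper(.advance(cur))
  if (!form %in% c("SELECT", "CONSTRUCT"))
    stop("unsupported query form: ", form)
  q <- list(form = form, prefixes = ns, distinct = FALSE, projection = list(),
            templates = list(), patterns = list(), filters = list(),
            groupBy = character(0), orderBy = list(), limit = NA_integer_)
  if (form == "SELECT") {
    if (.isKw(.peek(cur), "DISTINCT")) { .advance(cur); q$distinct <- TRUE }
    q$projection <- .parseProjection(cur)
    if (.isKw(.peek(cur), "WHERE")) .advance(cur)
    grp <- .parseGroupPattern(cur, ns)
    q$patterns <- grp$patterns
    q$filters <- grp$filters
    q <- .parseModifiers(cur, q)
  } else {
    .expect(cur, "{")
    tmpl <- .parseTriplesBlock(cur, ns, stopAt = "}")
    .expect(cur, "}")
    q$templates <- tmpl
    if (.isKw(.peek(cur), "WHERE")) .advance(cur)
    grp <- .parseGroupPattern(cur, ns)
    q$patterns <- grp$patterns
    q$filters <- grp$filters
  }
  q
}

.parseProjection <- function(cur) {
  items <- list()
  repeat {
    t <- .peek(cur)
    if (is.na(t) || .isKw(t, "WHERE") || t == "{") break
    if (startsWith(t, "?")) {
      .advance(cur)
      # pre-1.1 aggregate alias: "?x" never followed by AS; nothing to do
      items[[length(items) + 1L]] <- list(kind = "var", var = t)
    } else if (t == "(") {
      .advance(cur)
      items[[length(items) + 1L]] <- .parseAggregate(cur)
      .expect(cur, ")")
    } else if (.isKw(t, "COUNT")) {
      items[[length(items) + 1L]] <- .parseAggregate(cur)
    } else if (t == "*") {
      .advance(cur)
      items[[length(items) + 1L]] <- list(kind = "star")
    } else {
      stop("unsupported projection item: ", t)
    }
  }
  if (!length(items)) stop("empty SELECT projection")
  items
}

.parseAggregate <- function(cur) {
  fn <- .advance(cur)
  if (!.isKw(fn, "COUNT")) stop("unsupported aggregate: ", fn)
  .expect(cur, "(")
  distinct <- FALSE
  if (.isKw(.peek(cur), "DISTINCT")) { .advance(cur); distinct <- TRUE }
  arg <- .advance(cur)
  if (!(arg == "*" || startsWith(arg, "?")))
    stop("unsupported COUNT argument: ", arg)
  .expect(cur, ")")
  .expect(cur, "AS")
  alias <- .advance(cur)
  if (!startsWith(alias, "?")) stop("aggregate alias must be a variable")
  list(kind = "count", var = arg, distinct = distinct, alias = alias)
}

.parseGroupPattern <- function(cur, ns) {
  .expect(cur, "{")
  patterns <- list()
  filters <- list()
  repeat {
    t <- .peek(cur)
    if (is.na(t)) stop("unterminated group pattern: missing '}'")
    if (t == "}") { .advance(cur); break }
    if (.isKw(t, "FILTER")) {
      .advance(cur)
      filters[[length(filters) + 1L]] <- .parseFilter(cur, ns)
      if (identical(.peek(cur), ".")) .advance(cur)
    } else {
      patterns <- c(patterns, .parseTriplesBlock(cur, ns, stopAt = "}",
                                                 single = TRUE))
    }
  }
  list(patterns = patterns, filters = filters)
}

# one subject with its predicate-object list (single = TRUE), or a whole
# block of them (used for CONSTRUCT templates)
.parseTriplesBlock <- function(cur, ns, stopAt = "}", single = FALSE) {
  out <- list()
  repeat {
    t <- .peek(cur)
    if (is.na(t) || t == stopAt || .isKw(t, "FILTER")) break
    s <- .parseTermToken(.advance(cur), ns)
    repeat {
      p <- .parseTermToken(.advance(cur), ns)
      repeat {
        o <- .parseTermToken(.advance(cur), ns)
        out[[length(out) + 1L]] <- c(s, p, o)
        if (identical(.peek(cur), ",")) .advance(cur) else break
      }
      if (identical(.peek(cur), ";")) {
        .advance(cur)
        if (identical(.peek(cur), ".") || identical(.peek(cur), stopAt)) break
      } else break
    }
    if (identical(.peek(cur), ".")) .advance(cur)
    if (single) break
  }
  out
}

.parseTermToken <- function(tok, ns) {
  if (is.na(tok)) stop("unexpected end of query")
  if (startsWith(tok, "?")) return(tok)
  .encodeToken(tok, ns)
}

.parseFilter <- function(cur, ns) {
  t <- .peek(cur)
  wrapped <- FALSE
  if (t == "(") { .advance(cur); wrapped <- TRUE; t <- .peek(cur) }
  if (.isKw(t, "regex")) {
    .advance(cur)
    .expect(cur, "(")
    a <- .advance(cur)
    if (.isKw(a, "str")) {
      .expect(cur, "(")
      v <- .advance(cur)
      .expect(cur, ")")
    } else v <- a
    if (!startsWith(v, "?")) stop("FILTER regex argument must be a variable")
    .expect(cur, ",")
    pat <- .advance(cur)
    if (!startsWith(pat, "\"")) stop("FILTER regex pattern must be a string")
    icase <- FALSE
    if (identical(.peek(cur), ",")) {
      .advance(cur)
      flags <- .advance(cur)
      icase <- grepl("i", flags, fixed = TRUE)
    }
    .expect(cur, ")")
    if (wrapped) .expect(cur, ")")
    return(list(type = "regex", var = v,
                pattern = decodeTerm(.encodeToken(pat, ns))$value,
                icase = icase))
  }
  # ?v [NOT] IN ( value, ... )
  v <- .advance(cur)
  if (!startsWith(v, "?")) stop("unsupported FILTER expression near: ", v)
  negate <- FALSE
  t <- .advance(cur)
  if (.isKw(t, "NOT")) { negate <- TRUE; t <- .advance(cur) }
  if (!.isKw(t, "IN")) stop("unsupported FILTER operator: ", t)
  .expect(cur, "(")
  values <- character(0)
  repeat {
    values <- c(values, .encodeToken(.advance(cur), ns))
    t <- .advance(cur)
    if (t == ")") break
    if (t != ",") stop("malformed IN list near: ", t)
  }
  if (wrapped) .expect(cur, ")")
  list(type = "in", var = v, values = values, negate = negate)
}

.parseModifiers <- function(cur, q) {
  repeat {
    t <- .peek(cur)
    if (is.na(t)) break
    if (.isKw(t, "GROUP")) {
      .advance(cur); .expect(cur, "BY")
      repeat {
        v <- .peek(cur)
        if (is.na(v) || !startsWith(v, "?")) break
        q$groupBy <- c(q$groupBy, .advance(cur))
      }
    } else if (.isKw(t, "ORDER")) {
      .advance(cur); .expect(cur, "BY")
      repeat {
        t2 <- .peek(cur)
        if (is.na(t2)) break
        desc <- FALSE
        if (.isKw(t2, "DESC") || .isKw(t2, "ASC")) {
          desc <- .isKw(t2, "DESC")
          .advance(cur); .expect(cur, "(")
          v <- .advance(cur); .expect(cur, ")")
        } else if (startsWith(t2, "?")) {
          v <- .advance(cur)
        } else break
        q$orderBy[[length(q$orderBy) + 1L]] <- list(var = v, desc = desc)
      }
    } else if (.isKw(t, "LIMIT")) {
      .advance(cur)
      q$limit <- as.integer(.advance(cur))
    } else {
      stop("unsupported solution modifier: ", t)
    }
  }
  q
}
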