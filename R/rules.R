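#' @include sparql-engine.R gpml-rdf.R
NULL

#' Construct a rewrite rule
#'
#' @param name rule name.
#' @param patterns list of length-3 character vectors over the graphical
#'   layer; entries are encoded terms or variables ("?x").
#' @param templates list of length-3 character vectors over the biological
#'   layer; every variable must be bound by the patterns.
#' @param filters optional guards (see \linkS4class{RewriteRule}).
#' @return A \linkS4class{RewriteRule}.
#' @export
rewriteRule <- function(name, patterns, templates, filters = list()) {
  r <- new("RewriteRule", name = name, patterns = patterns,
           filters = filters, templates = templates)
  r
}

.instantiate <- function(rule, bindings) {
  n <- nrow(bindings)
  if (n == 0L) return(.emptyStatements())
  out <- lapply(rule@templates, function(tmpl) {
    get1 <- function(term) {
      if (startsWith(term, "?")) bindings[[term]] else rep(term, n)
    }
    data.frame(subject = get1(tmpl[1]), predicate = get1(tmpl[2]),
               object = get1(tmpl[3]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Apply rewrite rules to a graphical-layer graph
#'
#' Pure single-pass pattern matching: each rule is matched against the input
#' graph only (no rule consumes another's output), so application is
#' order-independent, monotone and idempotent.
#'
#' @param gpmlGraph a \linkS4class{TripleGraph} as produced by
#'   \code{\link{emitGpmlLayer}}.
#' @param rules list of \linkS4class{RewriteRule}; the built-in biological
#'   interpretation by default.
#' @param includeInput if TRUE (default) the result is the union of the
#'   input and the produced triples; if FALSE only the produced triples.
#' @return A \linkS4class{TripleGraph}.
#' @export
applyRules <- function(gpmlGraph, rules = defaultRules(),
                       includeInput = TRUE) {
  stopifnot(all(vapply(rules, is, logical(1), "RewriteRule")))
  produced <- lapply(rules, function(r) {
    .instantiate(r, solveBGP(gpmlGraph, r@patterns, r@filters))
  })
  parts <- c(if (includeInput) list(gpmlGraph@stm), produced)
  graphFromStatements(do.call(rbind, c(parts, list(.emptyStatements()))),
                      namespaces = gpmlGraph@ns)
}

.ruleTriple <- function(toks, ns, where) {
  if (length(toks) != 3L)
    stop("rule parse error (", where, "): expected 3 terms, got ",
         length(toks))
  vapply(toks, .parseTermToken, character(1), ns = ns)
}

.newRuleChecked <- function(name, patterns, templates, filters, where) {
  tryCatch(rewriteRule(name, patterns, templates, filters),
           error = function(e) stop("invalid rule '", name, "' (", where,
                                    "): ", conditionMessage(e),
                                    call. = FALSE))
}

# Parse the declarative rule dialect:
#   rule <name>
#   match
#     ?n rdf:type gpml:DataNode .
#     ...
#   filter ?x not in ("A", "B")      # optional, repeatable
#   emit
#     ?n rdf:type wp:Metabolite .
#   end
# '#' starts a comment; PREFIX lines at the top add to the default prefixes.
.parseDeclarativeRules <- function(lines) {
  ns <- defaultNamespaces()
  rules <- list()
  name <- NULL; section <- NULL
  patterns <- list(); templates <- list(); filters <- list()
  flush <- function() {
    if (!is.null(name)) {
      rules[[length(rules) + 1L]] <<- .newRuleChecked(
        name, patterns, templates, filters, paste0("line ", lineNo))
    }
    name <<- NULL; section <<- NULL
    patterns <<- list(); templates <<- list(); filters <<- list()
  }
  lineNo <- 0L
  for (raw in lines) {
    lineNo <- lineNo + 1L
    line <- sub('#(?=(?:[^"]*"[^"]*")*[^"]*$).*$', "", raw, perl = TRUE)
    line <- trimws(line)
    if (!nzchar(line)) next
    first <- tolower(sub("\\s.*$", "", line))
    if (first == "prefix") {
      m <- regmatches(line, regexec(
        "^[Pp][Rr][Ee][Ff][Ii][Xx]\\s+([A-Za-z][A-Za-z0-9_.-]*):\\s*<([^>]*)>", line))[[1]]
      if (length(m) == 0L) stop("line ", lineNo, ": malformed PREFIX")
      ns[[m[2]]] <- m[3]
    } else if (first == "rule") {
      if (!is.null(name))
        stop("line ", lineNo, ": rule '", name, "' not closed with 'end'")
      name <- trimws(sub("^\\S+\\s*", "", line))
      if (!nzchar(name)) stop("line ", lineNo, ": rule needs a name")
    } else if (first %in% c("match", "emit")) {
      section <- first
    } else if (first == "filter") {
      toks <- .tokenizeSPARQL(line)
      cur <- .newCursor(toks[-1])
      filters[[length(filters) + 1L]] <- .parseFilter(cur, ns)
    } else if (first == "end") {
      flush()
    } else {
      if (is.null(section))
        stop("line ", lineNo, ": statement outside match/emit section: ", line)
      toks <- .tokenizeSPARQL(sub("\\s*\\.\\s*$", "", line))
      tri <- .ruleTriple(toks, ns, paste0("line ", lineNo))
      if (section == "match") patterns[[length(patterns) + 1L]] <- tri
      else templates[[length(templates) + 1L]] <- tri
    }
  }
  if (!is.null(name))
    stop("rule '", name, "' not closed with 'end'")
  rules
}

# Parse one-or-more SPARQL CONSTRUCT queries into rewrite rules.  A comment
# line "# rule: <name>" directly above a CONSTRUCT names the rule.
.parseConstructRules <- function(lines) {
  isPrefix <- grepl("^\\s*PREFIX\\b", lines, ignore.case = TRUE)
  starts <- grep("^\\s*CONSTRUCT\\b", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no CONSTRUCT query found in rule file")
  prefixText <- paste(lines[isPrefix], collapse = "\n")
  bounds <- c(starts, length(lines) + 1L)
  rules <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:(bounds[k + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\s*PREFIX\\b", chunk, ignore.case = TRUE)]
    name <- sprintf("construct-%d", k)
    above <- lines[seq_len(starts[k] - 1L)]
    named <- grep("^\\s*#\\s*rule:\\s*\\S+", above, value = TRUE)
    if (length(named))
      name <- sub("^\\s*#\\s*rule:\\s*", "", named[length(named)])
    q <- parseSPARQL(paste(c(prefixText, chunk), collapse = "\n"))
    if (!identical(q$form, "CONSTRUCT"))
      stop("rule file chunk ", k, " is not a CONSTRUCT query")
    rules[[length(rules) + 1L]] <- .newRuleChecked(
      name, q$patterns, q$templates, q$filters, paste0("query ", k))
  }
  rules
}

#' Load rewrite rules from a file
#'
#' Two dialects are accepted and can be distinguished automatically: the
#' package's declarative rule syntax (\code{rule}/\code{match}/\code{emit}/
#' \code{end} blocks, see the shipped default at
#' \code{system.file("rules", "gpml-to-wp.rules", package = "pathwayRDF")}),
#' and SPARQL CONSTRUCT text (one rule per CONSTRUCT query).  A template
#' variable not bound by the match pattern is a load error.
#'
#' @param x file path or character scalar holding the rule text.
#' @return List of \linkS4class{RewriteRule}.
#' @export
loadRules <- function(x) {
  lines <- .readDocLines(x)
  body <- sub("#.*$", "", lines)
  if (any(grepl("^\\s*CONSTRUCT\\b", body, ignore.case = TRUE)))
    .parseConstructRules(lines)
  else
    .parseDeclarativeRules(lines)
}

#' Path of the shipped default rule file
#' @return File path string.
#' @export
defaultRuleFile <- function() {
  system.file("rules", "gpml-to-wp.rules", package = "pathwayRDF",
              mustWork = TRUE)
}
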