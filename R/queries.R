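#' @include sparql-engine.R rules.R
NULL

.queryDir <- function() system.file("queries", package = "pathwayRDF",
                                    mustWork = TRUE)

#' The shipped stock queries
#'
#' Loads the query files installed with the package: the example queries the
#' public WikiPathways SPARQL endpoint documents (species/pathway counts in
#' both the endpoint's historic aggregate spelling and normalized SPARQL 1.1,
#' gene products of a pathway, PubChem compounds), the federated example
#' queries (shipped as documentation only and refused by \code{runQuery}),
#' and the CONSTRUCT query translating the graphical layer into the
#' biological layer.
#'
#' @return Named list of \linkS4class{StoredQuery}.
#' @export
storedQueries <- function() {
  manifest <- yaml::read_yaml(file.path(.queryDir(), "queries.yaml"))
  qs <- lapply(manifest, function(m) {
    new("StoredQuery", name = m$name,
        sparql = paste(readLines(file.path(.queryDir(), m$file),
                                 warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n"),
        schema = as.character(unlist(m$schema)),
        federated = isTRUE(m$federated),
        description = m$description)
  })
  stats::setNames(qs, vapply(qs, function(q) q@name, character(1)))
}

#' Summarize the shipped queries
#'
#' @return data.frame with one row per stored query: name, federated flag,
#'   result schema and plain-language description.
#' @export
listQueries <- function() {
  qs <- storedQueries()
  data.frame(
    name = vapply(qs, function(q) q@name, character(1)),
    federated = vapply(qs, function(q) q@federated, logical(1)),
    schema = vapply(qs, function(q) paste(q@schema, collapse = ","),
                    character(1)),
    description = vapply(qs, function(q) q@description, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a stored (or ad hoc) SPARQL query against a graph
#'
#' SELECT queries return a data.frame of bindings (solution multiset, one
#' column per projected variable); CONSTRUCT queries return the constructed
#' \linkS4class{TripleGraph}.  Federated queries are documentation artifacts:
#' they reference remote endpoints and are refused with an error pointing to
#' \code{listQueries()}.
#'
#' @param graph a \linkS4class{TripleGraph}.
#' @param query a \linkS4class{StoredQuery}, the name of one, or SPARQL text.
#' @return data.frame or \linkS4class{TripleGraph}.
#' @export
runQuery <- function(graph, query) {
  if (is.character(query) && length(query) == 1L) {
    qs <- storedQueries()
    if (query %in% names(qs)) query <- qs[[query]]
    else if (!grepl("\\b(SELECT|CONSTRUCT)\\b", query, ignore.case = TRUE))
      stop("unknown stored query: ", query,
           " (see listQueries() for the shipped set)")
    else query <- new("StoredQuery", name = "<adhoc>", sparql = query,
                      schema = character(0), federated = FALSE,
                      description = "")
  }
  stopifnot(is(query, "StoredQuery"))
  if (query@federated)
    stop("query '", query@name, "' is federated (uses remote SERVICE ",
         "endpoints) and is shipped as documentation only; see listQueries()")
  q <- parseSPARQL(query@sparql,
                   extraPrefixes = c(graph@ns,
                                     defaultNamespaces()[
                                       setdiff(names(defaultNamespaces()),
                                               names(graph@ns))]))
  if (q$form == "CONSTRUCT") {
    rule <- rewriteRule(query@name, q$patterns, q$templates, q$filters)
    return(applyRules(graph, list(rule), includeInput = FALSE))
  }
  evalSelect(graph, q)
}

#' Print query results as TSV
#'
#' @param result data.frame as returned by \code{runQuery}.
#' @param con connection or file path; standard output by default.
#' @return \code{result}, invisibly.
#' @export
writeResultTSV <- function(result, con = stdout()) {
  utils::write.table(result, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(result)
}
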