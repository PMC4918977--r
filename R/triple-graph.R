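#' @include AllClasses.R
NULL

#' Construct a TripleGraph
#'
#' @param subject,predicate character vectors of URI strings (unencoded),
#'   recycled to a common length.
#' @param object character vector of encoded terms (see \code{\link{uriTerm}},
#'   \code{\link{litTerm}}); bare URI strings are accepted and encoded.
#' @param namespaces named character vector of prefix bindings.
#' @return A \linkS4class{TripleGraph}.
#' @examples
#' g <- tripleGraph("http://example.org/s", "http://example.org/p",
#'                  litTerm("hello", lang = "en"))
#' nTriples(g)
#' @export
tripleGraph <- function(subject = character(0), predicate = character(0),
                        object = character(0),
                        namespaces = defaultNamespaces()) {
  stm <- makeStatements(subject, predicate, object)
  new("TripleGraph", stm = unique(stm), ns = namespaces)
}

# Assemble an encoded statement table; subjects/predicates given as bare
# URIs, objects as encoded terms (bare URIs tolerated).
makeStatements <- function(subject, predicate, object) {
  n <- max(length(subject), length(predicate), length(object), 0L)
  if (n == 0L) return(.emptyStatements())
  subject <- rep_len(subject, n)
  predicate <- rep_len(predicate, n)
  object <- rep_len(object, n)
  bare <- !(startsWith(object, "<") | startsWith(object, "\""))
  object[bare] <- uriTerm(object[bare])
  data.frame(subject = uriTerm(subject), predicate = uriTerm(predicate),
             object = object, stringsAsFactors = FALSE)
}

.stmKey <- function(stm) paste(stm$subject, stm$predicate, stm$object,
                               sep = "\r")

#' @describeIn tripleGraph combine statement tables into one graph
#' @param ... statement data.frames (as from \code{makeStatements}) or
#'   TripleGraph objects.
#' @export
graphFromStatements <- function(..., namespaces = defaultNamespaces()) {
  parts <- lapply(list(...), function(x) {
    if (is(x, "TripleGraph")) x@stm else x
  })
  stm <- unique(do.call(rbind, c(parts, list(.emptyStatements()))))
  rownames(stm) <- NULL
  new("TripleGraph", stm = stm, ns = namespaces)
}

#' Union of triple graphs
#'
#' Set union of the statements; namespace bindings are merged (first binding
#' of a prefix wins).
#'
#' @param ... TripleGraph objects.
#' @return A \linkS4class{TripleGraph}.
#' @export
graphUnion <- function(...) {
  gs <- list(...)
  stopifnot(all(vapply(gs, is, logical(1), "TripleGraph")))
  ns <- unlist(lapply(gs, function(g) g@ns))
  ns <- ns[!duplicated(names(ns))]
  graphFromStatements(do.call(rbind, lapply(gs, function(g) g@stm)),
                      namespaces = ns)
}

#' Set equality of two triple graphs
#'
#' @param x,y TripleGraph objects.
#' @return TRUE iff both contain exactly the same statements (namespace
#'   bindings are not compared).
#' @export
graphEquals <- function(x, y) {
  setequal(.stmKey(x@stm), .stmKey(y@stm))
}

#' Set difference of two triple graphs
#' @param x,y TripleGraph objects.
#' @return TripleGraph with the statements of \code{x} not in \code{y}.
#' @export
graphDiff <- function(x, y) {
  keep <- !(.stmKey(x@stm) %in% .stmKey(y@stm))
  graphFromStatements(x@stm[keep, , drop = FALSE], namespaces = x@ns)
}

#' Test for a statement
#'
#' @param graph a TripleGraph.
#' @param subject,predicate bare URI strings, or NULL as wildcard.
#' @param object encoded term (or bare URI), or NULL as wildcard.
#' @return TRUE iff at least one matching statement exists.
#' @export
containsTriple <- function(graph, subject = NULL, predicate = NULL,
                           object = NULL) {
  stm <- graph@stm
  keep <- rep(TRUE, nrow(stm))
  if (!is.null(subject)) keep <- keep & stm$subject == uriTerm(subject)
  if (!is.null(predicate)) keep <- keep & stm$predicate == uriTerm(predicate)
  if (!is.null(object)) {
    o <- object
    if (!(startsWith(o, "<") || startsWith(o, "\""))) o <- uriTerm(o)
    keep <- keep & stm$object == o
  }
  any(keep)
}

#' Objects of matching statements
#'
#' @inheritParams containsTriple
#' @param decode if TRUE return plain values (URI strings / lexical forms),
#'   otherwise encoded terms.
#' @return Character vector of objects of the matching statements.
#' @export
tripleObjects <- function(graph, subject = NULL, predicate = NULL,
                          decode = FALSE) {
  stm <- graph@stm
  keep <- rep(TRUE, nrow(stm))
  if (!is.null(subject)) keep <- keep & stm$subject == uriTerm(subject)
  if (!is.null(predicate)) keep <- keep & stm$predicate == uriTerm(predicate)
  o <- stm$object[keep]
  if (decode) termValue(o) else o
}

#' @rdname nTriples
#' @export
setMethod("nTriples", "TripleGraph", function(x) nrow(x@stm))

#' @rdname statements
#' @export
setMethod("statements", "TripleGraph", function(x) {
  stm <- x@stm
  n <- nrow(stm)
  out <- data.frame(subject = termValue(stm$subject),
                    predicate = termValue(stm$predicate),
                    object = character(n), objectType = character(n),
                    datatype = rep(NA_character_, n),
                    lang = rep(NA_character_, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- decodeTerm(stm$object[i])
    out$object[i] <- d$value
    out$objectType[i] <- d$kind
    out$datatype[i] <- d$datatype
    out$lang[i] <- d$lang
  }
  out
})

#' @rdname namespaces
#' @export
setMethod("namespaces", "TripleGraph", function(x) x@ns)

setMethod("show", "TripleGraph", function(object) {
  cat(sprintf("TripleGraph with %d statement(s), %d namespace binding(s)\n",
              nrow(object@stm), length(object@ns)))
  n <- min(6L, nrow(object@stm))
  if (n > 0L) {
    stm <- object@stm[order(.stmKey(object@stm)), ][seq_len(n), ]
    for (i in seq_len(n))
      cat("  ", stm$subject[i], stm$predicate[i], stm$object[i], ".\n")
    if (nrow(object@stm) > n) cat("  ...\n")
  }
})
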