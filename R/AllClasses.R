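#' @include AllGenerics.R vocab.R
NULL

#' VocabTerm: one entry of the vocabulary registry
#'
#' Binds a prefixed name (e.g. \code{gpml:ZOrder}) to its full URI and records
#' whether the term is a class or a property.
#'
#' @slot prefix short namespace prefix.
#' @slot localName local part of the name.
#' @slot uri absolute URI.
#' @slot termKind \code{"Class"} or \code{"Property"}.
#' @export
setClass("VocabTerm",
         representation(prefix = "character", localName = "character",
                        uri = "character", termKind = "character"),
         validity = function(object) {
           msg <- character(0)
           if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", object@uri))
             msg <- c(msg, "uri must be an absolute IRI")
           if (!object@termKind %in% c("Class", "Property"))
             msg <- c(msg, "termKind must be 'Class' or 'Property'")
           if (length(msg)) msg else TRUE
         })

#' Full URI of a VocabTerm
#' @param term a \linkS4class{VocabTerm}.
#' @return Character scalar URI.
#' @export
termURI <- function(term) term@uri

setMethod("show", "VocabTerm", function(object) {
  cat(sprintf("%s:%s  <%s>  [%s]\n", object@prefix, object@localName,
              object@uri, object@termKind))
})

.emptyStatements <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), stringsAsFactors = FALSE)
}

#' TripleGraph: a set of RDF statements
#'
#' Statements are stored with subject, predicate and object in their encoded
#' N-Triples surface form (see \code{\link{uriTerm}}, \code{\link{litTerm}}),
#' with set semantics: adding an existing statement is a no-op.
#'
#' @slot stm data.frame with encoded columns subject, predicate, object.
#' @slot ns named character vector of namespace prefix bindings.
#' @export
setClass("TripleGraph",
         representation(stm = "data.frame", ns = "character"),
         prototype(stm = .emptyStatements(), ns = character(0)),
         validity = function(object) {
           st <- object@stm
           msg <- character(0)
           if (!all(c("subject", "predicate", "object") %in% names(st)))
             msg <- c(msg, "stm must have subject/predicate/object columns")
           else {
             if (nrow(st)) {
               if (!all(isURITerm(st$subject)))
                 msg <- c(msg, "all subjects must be URIs")
               if (!all(isURITerm(st$predicate)))
                 msg <- c(msg, "all predicates must be URIs")
               if (!all(isURITerm(st$object) | isLiteralTerm(st$object)))
                 msg <- c(msg, "objects must be URIs or literals")
             }
           }
           if (length(msg)) msg else TRUE
         })

#' PathwayModel: parsed in-memory GPML pathway
#'
#' Element tables keep document order.  \code{dataNodes} has columns graphId,
#' textLabel, nodeType, centerX, centerY, width, height, zOrder, xrefDb,
#' xrefId; \code{edges} has graphId, sourceRef, targetRef, arrowHead plus the
#' list columns anchors (character vectors of anchor graph ids) and waypoints
#' (two-column numeric matrices, one row per point); \code{labels} has
#' graphId, textLabel, centerX, centerY, width, height.
#'
#' @slot wpId WikiPathways accession ("WP" + digits).
#' @slot title pathway title.
#' @slot organismName organism as free text (NA when absent).
#' @slot organismTaxonUri identifiers.org taxonomy URI (NA when unknown).
#' @slot nodes data nodes table.
#' @slot edges interactions table.
#' @slot labels free labels table.
#' @slot sourceFile provenance string (file name or "<memory>").
#' @slot gpmlNamespace the XML namespace the document used.
#' @export
setClass("PathwayModel",
         representation(wpId = "character", title = "character",
                        organismName = "character",
                        organismTaxonUri = "character",
                        nodes = "data.frame", edges = "data.frame",
                        labels = "data.frame", sourceFile = "character",
                        gpmlNamespace = "character"),
         validity = function(object) {
           msg <- character(0)
           if (!grepl("^WP[0-9]+$", object@wpId))
             msg <- c(msg, "wpId must match WP<digits>")
           ids <- c(object@nodes$graphId, object@edges$graphId,
                    object@labels$graphId)
           if (anyDuplicated(ids))
             msg <- c(msg, paste0("duplicate graphId: ",
                                  paste(unique(ids[duplicated(ids)]),
                                        collapse = ", ")))
           if (length(msg)) msg else TRUE
         })

#' RewriteRule: one declarative graph-rewrite rule
#'
#' A conjunction of triple patterns over the graphical layer, optional value
#' guards, and a set of triple templates over the biological layer.  Patterns
#' and templates are lists of length-3 character vectors whose entries are
#' either encoded RDF terms or variables (\code{"?x"}).
#'
#' @slot name rule name.
#' @slot patterns match patterns (conjunctive).
#' @slot filters list of guards, each \code{list(var=, negate=, values=)}
#'   (values are encoded literal terms) or \code{list(var=, regex=, flags=)}.
#' @slot templates produced triple templates.
#' @export
setClass("RewriteRule",
         representation(name = "character", patterns = "list",
                        filters = "list", templates = "list"),
         validity = function(object) {
           vars <- function(x) {
             v <- unlist(x, use.names = FALSE)
             v[startsWith(v, "?")]
           }
           unbound <- setdiff(vars(object@templates), vars(object@patterns))
           if (length(unbound))
             paste0("template variable(s) not bound in match pattern: ",
                    paste(unbound, collapse = ", "))
           else TRUE
         })

setMethod("show", "RewriteRule", function(object) {
  cat(sprintf("RewriteRule '%s': %d pattern(s), %d filter(s) -> %d template(s)\n",
              object@name, length(object@patterns), length(object@filters),
              length(object@templates)))
})

#' IdentifierMap: many-to-many identifier unification table
#'
#' @slot records data.frame with columns sourceSystem, sourceId,
#'   unifiedSystem, unifiedId.
#' @slot uriPatterns named character vector, system name to identifiers.org
#'   URI template containing \code{$id}.
#' @export
setClass("IdentifierMap",
         representation(records = "data.frame", uriPatterns = "character"),
         validity = function(object) {
           need <- c("sourceSystem", "sourceId", "unifiedSystem", "unifiedId")
           msg <- character(0)
           if (!all(need %in% names(object@records)))
             msg <- c(msg, "records must have sourceSystem/sourceId/unifiedSystem/unifiedId")
           else {
             sys <- unique(object@records$unifiedSystem)
             miss <- setdiff(sys, names(object@uriPatterns))
             if (length(miss))
               msg <- c(msg, paste0("no URI template for system(s): ",
                                    paste(miss, collapse = ", ")))
           }
           if (length(msg)) msg else TRUE
         })

setMethod("show", "IdentifierMap", function(object) {
  cat(sprintf("IdentifierMap: %d record(s), %d source system(s) -> %s\n",
              nrow(object@records),
              length(unique(object@records$sourceSystem)),
              paste(sort(unique(object@records$unifiedSystem)),
                    collapse = ", ")))
})

#' StoredQuery: one shipped SPARQL query
#'
#' @slot name short query name.
#' @slot sparql the query text, verbatim.
#' @slot schema ordered result variable names (without "?").
#' @slot federated TRUE for queries that span remote endpoints via SERVICE;
#'   these are shipped as documentation and refused by \code{runQuery}.
#' @slot description one-line plain-language translation.
#' @export
setClass("StoredQuery",
         representation(name = "character", sparql = "character",
                        schema = "character", federated = "logical",
                        description = "character"),
         validity = function(object) {
           if (!object@federated && grepl("\\bSERVICE\\b", object@sparql,
                                          ignore.case = TRUE))
             "non-federated query must not contain a SERVICE clause"
           else TRUE
         })

setMethod("show", "StoredQuery", function(object) {
  cat(sprintf("StoredQuery '%s'%s: %s\n  vars: %s\n", object@name,
              if (object@federated) " [federated]" else "",
              object@description, paste(object@schema, collapse = ", ")))
})
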