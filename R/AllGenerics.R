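#' @include terms.R
NULL

#' Number of statements in a triple graph
#'
#' @param x a \linkS4class{TripleGraph}.
#' @return Integer statement count (set cardinality).
#' @export
setGeneric("nTriples", function(x) standardGeneric("nTriples"))

#' Statement table of a triple graph
#'
#' Returns the statements as a data.frame with one row per triple and columns
#' \code{subject}, \code{predicate}, \code{object}, \code{objectType}
#' (\code{"uri"} or \code{"literal"}), \code{datatype} and \code{lang}
#' (\code{NA} where not applicable).
#'
#' @param x a \linkS4class{TripleGraph}.
#' @return data.frame of decoded statements.
#' @export
setGeneric("statements", function(x) standardGeneric("statements"))

#' Namespace prefix bindings of a graph
#' @param x a \linkS4class{TripleGraph}.
#' @return Named character vector, prefix to base URI.
#' @export
setGeneric("namespaces", function(x) standardGeneric("namespaces"))

#' WikiPathways accession of a pathway model
#' @param x a \linkS4class{PathwayModel}.
#' @return Character scalar such as \code{"WP534"}.
#' @export
setGeneric("wpId", function(x) standardGeneric("wpId"))

#' Data nodes of a pathway model
#' @param x a \linkS4class{PathwayModel}.
#' @return data.frame with one row per data node.
#' @export
setGeneric("dataNodes", function(x) standardGeneric("dataNodes"))

#' Interaction edges of a pathway model
#' @param x a \linkS4class{PathwayModel}.
#' @return data.frame with one row per interaction.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' Free text labels of a pathway model
#' @param x a \linkS4class{PathwayModel}.
#' @return data.frame with one row per label.
#' @export
setGeneric("freeLabels", function(x) standardGeneric("freeLabels"))

#' Pathway title
#' @param x a \linkS4class{PathwayModel}.
#' @return Character scalar.
#' @export
setGeneric("pathwayTitle", function(x) standardGeneric("pathwayTitle"))

#' Organism annotation of a pathway model
#' @param x a \linkS4class{PathwayModel}.
#' @return Named list with \code{name} and \code{taxonUri} (either may be NA).
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))
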