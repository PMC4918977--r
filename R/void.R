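#' @include triple-graph.R vocab.R
NULL

CC_BY_3_URI <- "https://creativecommons.org/licenses/by/3.0/"

#' Build a VoID dataset description for a graph
#'
#' Generates the dataset header emitted next to every converted file: the
#' dataset type, title, license (Creative Commons Attribution 3.0 Unported by
#' default, matching the license of the pathway content), creation timestamp,
#' the statement count of the described graph (always computed here, never
#' taken on trust) and one \code{void:subset} link per per-pathway dataset.
#' The description is returned as its own graph, kept apart from the data.
#'
#' @param graph the data \linkS4class{TripleGraph} being described.
#' @param datasetUri URI naming the dataset.
#' @param title dataset title.
#' @param licenseUri license URI (non-optional).
#' @param created timestamp string (xsd:dateTime); injectable for
#'   reproducible builds, defaulting to the generation time in UTC.
#' @param subsetUris character vector of per-pathway dataset URIs.
#' @return A \linkS4class{TripleGraph} of VoID triples.
#' @examples
#' void <- buildVoid(tripleGraph(), "http://rdf.wikipathways.org/void",
#'                   title = "empty", created = "2016-06-23T00:00:00Z")
#' statements(void)
#' @export
buildVoid <- function(graph, datasetUri, title = "WikiPathways RDF",
                      licenseUri = CC_BY_3_URI, created = NULL,
                      subsetUris = character(0)) {
  if (is.null(licenseUri) || is.na(licenseUri) || !nzchar(licenseUri))
    stop("a license URI is required in the VoID header")
  if (is.null(created))
    created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  stm <- rbind(
    makeStatements(datasetUri, .tu("rdf:type"), uriTerm(.tu("void:Dataset"))),
    makeStatements(datasetUri, .tu("dcterms:title"), litTerm(title)),
    makeStatements(datasetUri, .tu("dcterms:license"), uriTerm(licenseUri)),
    makeStatements(datasetUri, .tu("dcterms:created"),
                   litTerm(created, datatype = XSD_DATETIME)),
    makeStatements(datasetUri, .tu("void:triples"), intTerm(nTriples(graph))))
  for (s in subsetUris)
    stm <- rbind(stm, makeStatements(datasetUri, .tu("void:subset"),
                                     uriTerm(s)))
  if (any(stm$subject %in% graph@stm$subject))
    warning("VoID dataset URI collides with a subject of the data graph")
  graphFromStatements(stm)
}
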