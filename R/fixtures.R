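#' @include triple-graph.R gpml-parse.R
NULL

#' In-paper worked-example fixtures
#'
#' \code{"glucose_node"} returns the path of the shipped minimal GPML
#' pathway (\code{WP534.gpml}) embedding the canonical glucose data node:
#' label "Glucose", graph id \code{dba83}, type Metabolite, center
#' (279.0, 468.0), size 112.0 x 20.0, z-order 32768, xref
#' \code{ChEBI:CHEBI:4167}.  \code{"wp534_intro"} returns the three-statement
#' reference graph stating that glucose is a member of the glycolysis
#' pathway, with the two English labels.
#'
#' @param name \code{"glucose_node"} or \code{"wp534_intro"}.
#' @return A file path (glucose_node) or a \linkS4class{TripleGraph}
#'   (wp534_intro).
#' @export
paperFixture <- function(name = c("glucose_node", "wp534_intro")) {
  name <- match.arg(name)
  if (name == "glucose_node")
    return(system.file("extdata", "WP534.gpml", package = "pathwayRDF",
                       mustWork = TRUE))
  pw <- "http://identifiers.org/wikipathways/WP534"
  glc <- "http://identifiers.org/chebi/CHEBI:4167"
  graphFromStatements(rbind(
    makeStatements(pw, .tu("skos:member"), uriTerm(glc)),
    makeStatements(pw, .tu("rdfs:label"),
                   litTerm("Glycolysis and Gluconeogenesis (Homo sapiens)",
                           lang = "en")),
    makeStatements(glc, .tu("rdfs:label"), litTerm("Glucose", lang = "en"))))
}
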