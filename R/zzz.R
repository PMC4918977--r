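#' pathwayRDF: pathway diagrams as linked data
#'
#' Converts GPML pathway diagrams into RDF in a graphical and a biological
#' vocabulary, unifies entity identifiers to canonical databases, attaches
#' VoID dataset metadata, and answers the stock SPARQL queries of the
#' WikiPathways endpoint.  See the package vignette for the conversion model
#' and its assumptions.
#'
#' @import methods
#' @keywords internal
"_PACKAGE"
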