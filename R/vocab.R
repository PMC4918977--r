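#' @include terms.R
NULL

# The two project vocabularies (graphical "gpml" layer, biological "wp"
# layer) plus the external terms they reuse, kept in one registry so every
# predicate emitted anywhere in the package resolves through a single table.

GPML_BASE <- "http://vocabularies.wikipathways.org/gpml#"
WP_BASE <- "http://vocabularies.wikipathways.org/wp#"
BIOPAX_BASE <- "http://www.biopax.org/release/biopax-level3.owl#"

#' Well-known namespace prefixes
#'
#' The prefix block used throughout: the two project vocabularies and the
#' external vocabularies they reuse.  These are also the default bindings of
#' every \linkS4class{TripleGraph} and the prefixes a stored query may use
#' without declaring them (the public endpoint behaved the same way).
#'
#' @return Named character vector mapping prefix to base URI.
#' @export
defaultNamespaces <- function() {
  c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    xsd = "http://www.w3.org/2001/XMLSchema#",
    dc = "http://purl.org/dc/elements/1.1/",
    dcterms = "http://purl.org/dc/terms/",
    skos = "http://www.w3.org/2004/02/skos/core#",
    void = "http://rdfs.org/ns/void#",
    gpml = GPML_BASE,
    wp = WP_BASE,
    wprdf = "http://rdf.wikipathways.org/",
    wpid = "http://identifiers.org/wikipathways/")
}

.registryRow <- function(prefix, local, kind) {
  data.frame(prefix = prefix, localName = local, kind = kind,
             stringsAsFactors = FALSE)
}

#' Build a vocabulary registry
#'
#' Normally the built-in registry (\code{defaultVocabulary()}) is all that is
#' needed; custom base URIs support offline mirrors of the vocabulary
#' documents.
#'
#' @param gpmlBase,wpBase base URIs of the two vocabularies.
#' @return data.frame with columns prefix, localName, kind ("Class" or
#'   "Property") and uri.
#' @export
makeVocabRegistry <- function(gpmlBase = GPML_BASE, wpBase = WP_BASE) {
  gpmlClasses <- c("Pathway", "DataNode", "Interaction", "Label")
  gpmlProps <- c("graphId", "ZOrder", "centerX", "centerY", "width", "height",
                 "dataNodeType", "pathway", "organism", "organismName",
                 "xrefDataSource", "xrefId", "xrefUri", "arrowHead", "points",
                 "sourceRef", "targetRef", "anchorRef", "anchor")
  wpClasses <- c("Pathway", "DataNode", "GeneProduct", "Metabolite", "Protein",
                 "Rna", "Complex", "Label", "Interaction",
                 "DirectedInteraction", "Inhibition", "Conversion", "Catalysis")
  wpProps <- c("organism", "organismName", "source", "target", "participants",
               "bdbEntrezGene", "bdbEnsembl", "bdbUniprot", "bdbHmdb",
               "bdbChemspider")
  reg <- rbind(
    .registryRow("gpml", gpmlClasses, "Class"),
    .registryRow("gpml", gpmlProps, "Property"),
    .registryRow("wp", wpClasses, "Class"),
    .registryRow("wp", wpProps, "Property"),
    .registryRow("dc", c("title", "identifier", "source"), "Property"),
    .registryRow("dcterms",
                 c("isPartOf", "identifier", "title", "license", "created"),
                 "Property"),
    .registryRow("rdf", "type", "Property"),
    .registryRow("rdf", "Property", "Class"),
    .registryRow("rdfs", c("label", "isDefinedBy"), "Property"),
    .registryRow("rdfs", "Class", "Class"),
    .registryRow("skos", c("member", "exactMatch", "closeMatch"), "Property"),
    .registryRow("void", "Dataset", "Class"),
    .registryRow("void", c("triples", "subset"), "Property"),
    .registryRow("xsd",
                 c("string", "integer", "float", "boolean", "dateTime"),
                 "Class"))
  ns <- defaultNamespaces()
  ns[["gpml"]] <- gpmlBase
  ns[["wp"]] <- wpBase
  reg$uri <- paste0(unname(ns[reg$prefix]), reg$localName)
  if (anyDuplicated(reg$uri))
    stop("vocabulary registry assigns one URI to two terms")
  if (anyDuplicated(paste(reg$prefix, reg$localName)))
    stop("duplicate (prefix, localName) in vocabulary registry")
  reg
}

#' The built-in vocabulary registry
#' @return data.frame as from \code{makeVocabRegistry}.
#' @export
defaultVocabulary <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- makeVocabRegistry()
    reg
  }
})

#' Resolve a prefixed name against the vocabulary registry
#'
#' @param prefixedName string such as \code{"skos:member"}.
#' @param registry a registry data.frame, by default the built-in one.
#' @return A \linkS4class{VocabTerm}.
#' @examples
#' termURI(resolveTerm("skos:member"))
#' @export
resolveTerm <- function(prefixedName, registry = defaultVocabulary()) {
  parts <- strsplit(prefixedName, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("not a prefixed name: ", prefixedName)
  hit <- registry[registry$prefix == parts[1] & registry$localName == parts[2], ]
  if (nrow(hit) != 1L)
    stop("unknown vocabulary term: ", prefixedName)
  new("VocabTerm", prefix = hit$prefix, localName = hit$localName,
      uri = hit$uri, termKind = hit$kind)
}

#' Reverse-resolve a URI to its registered prefixed name
#'
#' @param uri absolute URI string.
#' @param registry a registry data.frame.
#' @return Prefixed name string, or \code{NA} when the URI is not registered.
#' @export
termFromURI <- function(uri, registry = defaultVocabulary()) {
  i <- match(uri, registry$uri)
  ifelse(is.na(i), NA_character_,
         paste0(registry$prefix[i], ":", registry$localName[i]))
}

# fast internal lookup: prefixed name -> bare URI string
.tu <- local({
  cache <- NULL
  function(prefixedName) {
    if (is.null(cache)) {
      reg <- defaultVocabulary()
      cache <<- stats::setNames(reg$uri, paste0(reg$prefix, ":", reg$localName))
    }
    u <- cache[prefixedName]
    if (anyNA(u)) stop("unknown vocabulary term: ",
                       paste(prefixedName[is.na(u)], collapse = ", "))
    unname(u)
  }
})

#' Built-in SKOS alignment links
#'
#' A deliberately small seed set linking the biological-layer vocabulary to
#' BioPAX level 3; extend it with \code{loadAlignmentTSV}.
#'
#' @return data.frame with columns wp_term, external_uri, relation.
#' @export
defaultAlignments <- function() {
  data.frame(
    wp_term = c("wp:Pathway", "wp:DirectedInteraction"),
    external_uri = paste0(BIOPAX_BASE, c("Pathway", "Conversion")),
    relation = c("closeMatch", "closeMatch"),
    stringsAsFactors = FALSE)
}

#' Export a vocabulary as RDF
#'
#' Emits class/property declaration triples for every registered term of the
#' requested vocabulary (type, label, isDefinedBy), plus one SKOS similarity
#' triple per alignment link whose subject term belongs to that vocabulary.
#'
#' @param which \code{"gpml"} or \code{"wp"}.
#' @param registry a vocabulary registry data.frame.
#' @param alignments alignment links (see \code{\link{defaultAlignments}}).
#' @return A \linkS4class{TripleGraph}.
#' @export
exportVocabulary <- function(which = c("gpml", "wp"),
                             registry = defaultVocabulary(),
                             alignments = defaultAlignments()) {
  which <- match.arg(which)
  terms <- registry[registry$prefix == which, , drop = FALSE]
  rdfType <- registry$uri[registry$prefix == "rdf" &
                            registry$localName == "type"]
  rdfsLabel <- registry$uri[registry$prefix == "rdfs" &
                              registry$localName == "label"]
  rdfsDef <- registry$uri[registry$prefix == "rdfs" &
                            registry$localName == "isDefinedBy"]
  classURI <- registry$uri[registry$prefix == "rdfs" &
                             registry$localName == "Class"]
  propURI <- registry$uri[registry$prefix == "rdf" &
                            registry$localName == "Property"]
  bases <- substr(terms$uri, 1L, nchar(terms$uri) - nchar(terms$localName))
  base <- sub("#$", "", unique(bases))[1]
  stm <- .emptyStatements()
  if (nrow(terms)) {
    stm <- rbind(
      makeStatements(terms$uri, rdfType,
                     uriTerm(ifelse(terms$kind == "Class", classURI,
                                    propURI))),
      makeStatements(terms$uri, rdfsLabel, litTerm(terms$localName)),
      makeStatements(terms$uri, rdfsDef, uriTerm(base)))
  }
  if (!is.null(alignments) && nrow(alignments)) {
    keep <- startsWith(alignments$wp_term, paste0(which, ":"))
    al <- alignments[keep, , drop = FALSE]
    for (i in seq_len(nrow(al))) {
      t <- resolveTerm(al$wp_term[i], registry)
      rel <- registry$uri[registry$prefix == "skos" &
                            registry$localName == al$relation[i]]
      stm <- rbind(stm, makeStatements(t@uri, rel,
                                       uriTerm(al$external_uri[i])))
    }
  }
  graphFromStatements(stm)
}

#' Load alignment links from a TSV file
#'
#' Expected columns: \code{wp_term} (prefixed name), \code{external_uri},
#' \code{relation} (\code{exactMatch} or \code{closeMatch}); lines starting
#' with \code{#} are comments.
#'
#' @param path file path or connection.
#' @param registry vocabulary registry the wp_term column must resolve in.
#' @return data.frame in the shape of \code{defaultAlignments()}.
#' @export
loadAlignmentTSV <- function(path, registry = defaultVocabulary()) {
  lines <- .readDocLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]  # URIs may contain '#'
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           header = TRUE, stringsAsFactors = FALSE)
  need <- c("wp_term", "external_uri", "relation")
  if (!all(need %in% names(tab)))
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(tab$relation, c("exactMatch", "closeMatch"))
  if (length(bad))
    stop("unsupported alignment relation(s): ", paste(bad, collapse = ", "))
  for (t in tab$wp_term) resolveTerm(t, registry)  # errors on unknown terms
  tab[need]
}
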