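#' @include triple-graph.R vocab.R gpml-parse.R
NULL

.UNIFIED_SYSTEMS <- c("EntrezGene", "Ensembl", "UniProt", "HMDB", "ChemSpider")

#' Default identifiers.org URI templates
#'
#' Maps identifier system names (GPML \code{Database} attribute spellings and
#' the unified-system names) to identifiers.org URI templates; \code{$id} is
#' replaced by the raw accession.  Overridable: pass a modified vector to the
#' minting and emission functions, or load one from YAML with
#' \code{\link{loadUriPatterns}}.
#'
#' @return Named character vector of templates.
#' @export
defaultUriPatterns <- function() {
  c("ChEBI" = "http://identifiers.org/chebi/$id",
    "HMDB" = "http://identifiers.org/hmdb/$id",
    "ChemSpider" = "http://identifiers.org/chemspider/$id",
    "PubChem-compound" = "http://identifiers.org/pubchem.compound/$id",
    "Entrez Gene" = "http://identifiers.org/ncbigene/$id",
    "EntrezGene" = "http://identifiers.org/ncbigene/$id",
    "Ensembl" = "http://identifiers.org/ensembl/$id",
    "UniProt" = "http://identifiers.org/uniprot/$id",
    "Uniprot-TrEMBL" = "http://identifiers.org/uniprot/$id",
    "WikiPathways" = "http://identifiers.org/wikipathways/$id",
    "Taxonomy" = "http://identifiers.org/taxonomy/$id")
}

#' Load identifiers.org URI templates from YAML
#'
#' Expects a flat mapping of system name to template (each containing
#' \code{$id}).
#'
#' @param path YAML file path.
#' @return Named character vector of templates.
#' @export
loadUriPatterns <- function(path) {
  y <- yaml::read_yaml(path)
  pat <- vapply(y, as.character, character(1))
  bad <- names(pat)[!grepl("$id", pat, fixed = TRUE)]
  if (length(bad))
    stop("URI template without $id slot for: ", paste(bad, collapse = ", "))
  pat
}

#' Mint an identifiers.org URI
#'
#' Deterministic: the template of the system is filled with the raw accession
#' (e.g. \code{("ChEBI", "CHEBI:4167")} gives
#' \code{http://identifiers.org/chebi/CHEBI:4167}).
#'
#' @param system identifier system name (must have a registered template).
#' @param id accession string.
#' @param patterns template table, by default \code{defaultUriPatterns()}.
#' @return URI string (same length as \code{id}).
#' @export
mintIdentifiersOrgUri <- function(system, id,
                                  patterns = defaultUriPatterns()) {
  n <- max(length(system), length(id))
  system <- rep_len(system, n); id <- rep_len(id, n)
  miss <- setdiff(unique(system), names(patterns))
  if (length(miss))
    stop("no identifiers.org URI template registered for system(s): ",
         paste(miss, collapse = ", "))
  tpl <- unname(patterns[system])
  mapply(function(t, i) sub("$id", i, t, fixed = TRUE), tpl, id,
         USE.NAMES = FALSE)
}

#' Construct an IdentifierMap
#'
#' @param records data.frame with columns sourceSystem, sourceId,
#'   unifiedSystem, unifiedId; duplicate rows collapse.
#' @param uriPatterns URI template table.
#' @return An \linkS4class{IdentifierMap}.
#' @export
identifierMap <- function(records = data.frame(sourceSystem = character(0),
                                               sourceId = character(0),
                                               unifiedSystem = character(0),
                                               unifiedId = character(0),
                                               stringsAsFactors = FALSE),
                          uriPatterns = defaultUriPatterns()) {
  records <- unique(records)
  rownames(records) <- NULL
  new("IdentifierMap", records = records, uriPatterns = uriPatterns)
}

#' Load an identifier mapping TSV
#'
#' Four tab-separated columns (source_system, source_id, unified_system,
#' unified_id), no header, \code{#} starts a comment line.  Duplicate rows
#' collapse; an unknown unified system is a load error.
#'
#' @param path file path or connection.
#' @param uriPatterns URI template table for the systems involved.
#' @return An \linkS4class{IdentifierMap}.
#' @export
loadMappingTSV <- function(path, uriPatterns = defaultUriPatterns()) {
  lines <- .readDocLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(identifierMap(uriPatterns = uriPatterns))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 4L))
    stop("mapping TSV line ", which(nc != 4L)[1],
         ": expected 4 tab-separated columns, found ", nc[nc != 4L][1])
  m <- do.call(rbind, parts)
  rec <- data.frame(sourceSystem = m[, 1], sourceId = m[, 2],
                    unifiedSystem = m[, 3], unifiedId = m[, 4],
                    stringsAsFactors = FALSE)
  badSys <- setdiff(unique(rec$unifiedSystem), .UNIFIED_SYSTEMS)
  if (length(badSys))
    stop("unknown unified system(s) in mapping TSV: ",
         paste(badSys, collapse = ", "),
         " (expected one of ", paste(.UNIFIED_SYSTEMS, collapse = ", "), ")")
  identifierMap(rec, uriPatterns)
}

#' Look up the unified identifiers of a source identifier
#'
#' @param map an \linkS4class{IdentifierMap}.
#' @param system,id the source identifier.
#' @return data.frame with columns unifiedSystem, unifiedId (zero rows when
#'   unmapped).
#' @export
lookupUnified <- function(map, system, id) {
  rec <- map@records
  hit <- rec[rec$sourceSystem == system & rec$sourceId == id,
             c("unifiedSystem", "unifiedId"), drop = FALSE]
  rownames(hit) <- NULL
  hit
}

# GPML Database attribute spellings of the unified systems (self-mapping)
.SELF_SYSTEM <- c("Entrez Gene" = "EntrezGene", "EntrezGene" = "EntrezGene",
                  "Ensembl" = "Ensembl", "UniProt" = "UniProt",
                  "Uniprot-TrEMBL" = "UniProt", "HMDB" = "HMDB",
                  "ChemSpider" = "ChemSpider")

#' The default unification policy
#'
#' Gene-type nodes (GeneProduct, Protein, Rna) take the gene predicates
#' (\code{wp:bdbEntrezGene}, \code{wp:bdbEnsembl}, \code{wp:bdbUniprot});
#' metabolite nodes take the compound predicates (\code{wp:bdbHmdb},
#' \code{wp:bdbChemspider}).  Other node classes receive no unified-identifier
#' triples.
#'
#' @return List with elements \code{geneTargets}, \code{compoundTargets}
#'   (named character vectors, unified system to predicate term) and
#'   \code{routing} (node type to \code{"gene"}/\code{"compound"}/NA).
#' @export
unificationPolicy <- function() {
  list(
    geneTargets = c(EntrezGene = "wp:bdbEntrezGene", Ensembl = "wp:bdbEnsembl",
                    UniProt = "wp:bdbUniprot"),
    compoundTargets = c(HMDB = "wp:bdbHmdb", ChemSpider = "wp:bdbChemspider"),
    routing = c(GeneProduct = "gene", Protein = "gene", Rna = "gene",
                Metabolite = "compound", Pathway = NA, Complex = NA,
                Unknown = NA))
}

# unified (system, id) pairs a node routes to, self-mapping included,
# restricted by the policy; returns data.frame(unifiedSystem, unifiedId)
.unifiedPairsForNode <- function(nodeType, xrefDb, xrefId, map, policy) {
  route <- policy$routing[[nodeType]]
  empty <- data.frame(unifiedSystem = character(0), unifiedId = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(xrefDb) || is.na(route)) return(empty)
  targets <- names(switch(route, gene = policy$geneTargets,
                          compound = policy$compoundTargets))
  pairs <- lookupUnified(map, xrefDb, xrefId)
  if (xrefDb %in% names(.SELF_SYSTEM)) {
    self <- .SELF_SYSTEM[[xrefDb]]
    pairs <- rbind(pairs, data.frame(unifiedSystem = self, unifiedId = xrefId,
                                     stringsAsFactors = FALSE))
  }
  pairs <- unique(pairs[pairs$unifiedSystem %in% targets, , drop = FALSE])
  rownames(pairs) <- NULL
  pairs
}

#' Emit unified-identifier triples for a pathway model
#'
#' For every xref-annotated data node, emits one \code{wp:bdb*} triple per
#' mapped unified identifier (the predicate chosen by the policy's gene /
#' compound routing, the object the identifiers.org URI of the unified
#' identifier), plus the original-identifier triple \code{dc:identifier}
#' with the identifiers.org URI of the curator's xref.  A node whose xref is
#' already in a unified system also gets a \code{wp:bdb*} triple to itself.
#' Unmapped xrefs yield only the \code{dc:identifier} triple, with a message.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @param map an \linkS4class{IdentifierMap}.
#' @param policy as from \code{\link{unificationPolicy}}.
#' @param subjectPolicy subject URI policy (see
#'   \code{\link{subjectUriPolicy}}); must match the one used for the RDF
#'   layers so the triples attach to the same subjects.
#' @return A \linkS4class{TripleGraph}.
#' @export
emitUnifiedTriples <- function(model, map, policy = unificationPolicy(),
                               subjectPolicy = subjectUriPolicy()) {
  nd <- model@nodes
  stm <- .emptyStatements()
  pred <- c(policy$geneTargets, policy$compoundTargets)
  for (i in seq_len(nrow(nd))) {
    if (is.na(nd$xrefDb[i])) next
    subj <- .nodeSubjectURI(model, i, subjectPolicy, map@uriPatterns)
    orig <- tryCatch(
      mintIdentifiersOrgUri(nd$xrefDb[i], nd$xrefId[i], map@uriPatterns),
      error = function(e) NA_character_)
    if (!is.na(orig))
      stm <- rbind(stm, makeStatements(subj, .tu("dc:identifier"),
                                       uriTerm(orig)))
    pairs <- .unifiedPairsForNode(nd$nodeType[i], nd$xrefDb[i], nd$xrefId[i],
                                  map, policy)
    if (nrow(pairs) == 0L) {
      if (!is.na(policy$routing[[nd$nodeType[i]]]))
        message("node ", nd$graphId[i], " (", nd$xrefDb[i], ":", nd$xrefId[i],
                "): no unified mapping")
      next
    }
    uris <- mintIdentifiersOrgUri(pairs$unifiedSystem, pairs$unifiedId,
                                  map@uriPatterns)
    stm <- rbind(stm, makeStatements(subj, .tu(pred[pairs$unifiedSystem]),
                                     uriTerm(uris)))
  }
  graphFromStatements(stm)
}
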