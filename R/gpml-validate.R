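#' @include gpml-parse.R
NULL

.violation <- function(graphId, rule, message) {
  data.frame(graphId = graphId, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a PathwayModel against the GPML invariants
#'
#' Validation never raises: every broken invariant is reported as one row
#' naming the offending element and the rule.
#'
#' Rules checked: the accession pattern (\code{WP} + digits); graph-id
#' uniqueness across nodes, interactions and labels; strictly positive data
#' node dimensions; non-negative label dimensions; at least two waypoints per
#' interaction; and that interaction endpoint references resolve to an
#' existing graph id (of a node, label, interaction, or an anchor).
#'
#' @param model a \linkS4class{PathwayModel}.
#' @return data.frame with columns graphId, rule, message; zero rows iff the
#'   model is valid.
#' @export
validatePathway <- function(model) {
  out <- .violation(character(0), character(0), character(0))
  if (!grepl("^WP[0-9]+$", model@wpId))
    out <- rbind(out, .violation("<pathway>", "wp_id_pattern",
                                 paste0("wpId '", model@wpId,
                                        "' does not match WP<digits>")))
  ids <- c(model@nodes$graphId, model@edges$graphId, model@labels$graphId)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup)
    out <- rbind(out, .violation(d, "unique_graph_id",
                                 paste0("graphId '", d, "' used by ",
                                        sum(ids == d), " elements")))
  nd <- model@nodes
  bad <- which(!(nd$width > 0 & nd$height > 0))
  for (i in bad)
    out <- rbind(out, .violation(nd$graphId[i], "node_dimensions",
                                 "data node width and height must be > 0"))
  lb <- model@labels
  bad <- which(!(lb$width >= 0 & lb$height >= 0))
  for (i in bad)
    out <- rbind(out, .violation(lb$graphId[i], "label_dimensions",
                                 "label width and height must be >= 0"))
  ed <- model@edges
  anchorIds <- unlist(ed$anchors)
  known <- c(ids, anchorIds)
  for (i in seq_len(nrow(ed))) {
    wp <- ed$waypoints[[i]]
    if (is.null(wp) || nrow(wp) < 2L)
      out <- rbind(out, .violation(ed$graphId[i], "waypoint_count",
                                   "interaction needs at least 2 waypoints"))
    for (ref in c(ed$sourceRef[i], ed$targetRef[i])) {
      if (!is.na(ref) && !ref %in% known)
        out <- rbind(out, .violation(ed$graphId[i], "dangling_ref",
                                     paste0("endpoint reference '", ref,
                                            "' resolves to no element")))
    }
  }
  rownames(out) <- NULL
  out
}
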