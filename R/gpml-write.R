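#' @include gpml-parse.R
NULL

.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, digits = 12, scientific = FALSE, trim = TRUE)
    if (!grepl(".", s, fixed = TRUE)) s <- paste0(s, ".0")
    s
  }, character(1))
}

#' Write a PathwayModel as GPML
#'
#' Produces a GPML document that \code{\link{parseGPML}} reads back to a model
#' equal field-for-field, including the WikiPathways accession, which GPML
#' itself does not carry: the writer stores it in a PathVisio-style dynamic
#' \code{<Attribute Key="WikiPathwaysID">} child of the Pathway element.
#'
#' @param model a \linkS4class{PathwayModel} satisfying its invariants.
#' @param path optional output file; when NULL the XML is returned as a
#'   character scalar.
#' @return The GPML document (character) or \code{path} invisibly.
#' @export
writeGPML <- function(model, path = NULL) {
  viol <- validatePathway(model)
  if (nrow(viol))
    stop("model violates GPML invariants: ",
         paste(sprintf("[%s] %s", viol$graphId, viol$rule), collapse = "; "))
  doc <- xml2::xml_new_root("Pathway", xmlns = model@gpmlNamespace,
                            Name = model@title)
  if (!is.na(model@organismName))
    xml2::xml_set_attr(doc, "Organism", model@organismName)
  xml2::xml_add_child(doc, "Attribute", Key = "WikiPathwaysID",
                      Value = model@wpId)

  nd <- model@nodes
  for (i in seq_len(nrow(nd))) {
    el <- xml2::xml_add_child(doc, "DataNode", TextLabel = nd$textLabel[i],
                              GraphId = nd$graphId[i], Type = nd$nodeType[i])
    xml2::xml_add_child(el, "Graphics",
                        CenterX = .fmtNum(nd$centerX[i]),
                        CenterY = .fmtNum(nd$centerY[i]),
                        Width = .fmtNum(nd$width[i]),
                        Height = .fmtNum(nd$height[i]),
                        ZOrder = format(nd$zOrder[i], scientific = FALSE))
    if (!is.na(nd$xrefDb[i]))
      xml2::xml_add_child(el, "Xref", Database = nd$xrefDb[i],
                          ID = nd$xrefId[i])
  }

  ed <- model@edges
  for (i in seq_len(nrow(ed))) {
    el <- xml2::xml_add_child(doc, "Interaction", GraphId = ed$graphId[i])
    g <- xml2::xml_add_child(el, "Graphics")
    wp <- ed$waypoints[[i]]
    for (k in seq_len(nrow(wp))) {
      pt <- xml2::xml_add_child(g, "Point", X = .fmtNum(wp[k, 1]),
                                Y = .fmtNum(wp[k, 2]))
      if (k == 1L && !is.na(ed$sourceRef[i]))
        xml2::xml_set_attr(pt, "GraphRef", ed$sourceRef[i])
      if (k == nrow(wp)) {
        if (!is.na(ed$targetRef[i]))
          xml2::xml_set_attr(pt, "GraphRef", ed$targetRef[i])
        xml2::xml_set_attr(pt, "ArrowHead", ed$arrowHead[i])
      }
    }
    for (a in ed$anchors[[i]])
      xml2::xml_add_child(g, "Anchor", GraphId = a, Shape = "None")
  }

  lb <- model@labels
  for (i in seq_len(nrow(lb))) {
    el <- xml2::xml_add_child(doc, "Label", TextLabel = lb$textLabel[i],
                              GraphId = lb$graphId[i])
    xml2::xml_add_child(el, "Graphics",
                        CenterX = .fmtNum(lb$centerX[i]),
                        CenterY = .fmtNum(lb$centerY[i]),
                        Width = .fmtNum(lb$width[i]),
                        Height = .fmtNum(lb$height[i]))
  }

  txt <- as.character(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
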