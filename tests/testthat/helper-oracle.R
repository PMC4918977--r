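# Independent oracles: a naive backtracking pattern join (no shared code
# with the merge-based engine), an element counter over raw XML text, and
# the manifest-based unified-identifier fan-out count.

# terms in patterns: encoded strings or "?var"; returns list of bindings
oracleSolve <- function(graph, patterns, filters = list()) {
  stm <- graph@stm
  results <- list()
  recurse <- function(i, binding) {
    if (i > length(patterns)) {
      for (f in filters) {
        val <- binding[[f$var]]
        ok <- if (f$type == "regex") {
          grepl(f$pattern, pathwayRDF::decodeTerm(val)$value,
                ignore.case = isTRUE(f$icase)) ||
            (startsWith(val, "<") &&
               grepl(f$pattern, substr(val, 2, nchar(val) - 1),
                     ignore.case = isTRUE(f$icase)))
        } else {
          inSet <- val %in% f$values
          if (isTRUE(f$negate)) !inSet else inSet
        }
        if (!ok) return(invisible(NULL))
      }
      results[[length(results) + 1L]] <<- binding
      return(invisible(NULL))
    }
    pat <- patterns[[i]]
    for (r in seq_len(nrow(stm))) {
      row <- c(stm$subject[r], stm$predicate[r], stm$object[r])
      b2 <- binding
      ok <- TRUE
      for (k in 1:3) {
        t <- pat[k]
        if (startsWith(t, "?")) {
          if (!is.null(b2[[t]])) {
            if (b2[[t]] != row[k]) { ok <- FALSE; break }
          } else b2[[t]] <- row[k]
        } else if (t != row[k]) { ok <- FALSE; break }
      }
      if (ok) recurse(i + 1L, b2)
    }
  }
  recurse(1L, list())
  results
}

# project bindings to plain values, one row per solution
oracleProject <- function(solutions, vars) {
  if (!length(solutions))
    return(stats::setNames(
      as.data.frame(matrix(character(0), ncol = length(vars))),
      sub("^\\?", "", vars)))
  rows <- lapply(solutions, function(b)
    vapply(vars, function(v) {
      t <- b[[v]]
      if (startsWith(t, "<")) substr(t, 2, nchar(t) - 1)
      else pathwayRDF::decodeTerm(t)$value
    }, character(1)))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- sub("^\\?", "", vars)
  rownames(out) <- NULL
  out
}

sortRows <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_rows <- function(a, b) {
  for (col in names(a)) a[[col]] <- as.character(a[[col]])
  for (col in names(b)) b[[col]] <- as.character(b[[col]])
  expect_equal(sortRows(a), sortRows(b))
}

# count <Tag ...> occurrences in raw XML text, independent of the parser
countXmlElements <- function(xmlText, tag) {
  sum(lengths(regmatches(xmlText,
                         gregexpr(paste0("<", tag, "[ />]"), xmlText))))
}

uv <- function(term) pathwayRDF::uriTerm(term)  # shorthand in pattern specs

tu <- function(x) pathwayRDF::uriTerm(pathwayRDF:::.tu(x))

# expected wp:bdb* triple count per pathway from the generator manifest:
# routing-filtered mapping fan-out plus self-mapping, deduplicated
manifestBdbCount <- function(manifest) {
  policy <- pathwayRDF::unificationPolicy()
  selfMap <- c("Entrez Gene" = "EntrezGene", "Ensembl" = "Ensembl",
               "UniProt" = "UniProt", "Uniprot-TrEMBL" = "UniProt",
               "HMDB" = "HMDB", "ChemSpider" = "ChemSpider")
  total <- 0L
  for (e in manifest$pathways) {
    nd <- e$nodes
    for (i in seq_len(nrow(nd))) {
      route <- policy$routing[[nd$type[i]]]
      if (is.na(nd$xrefDb[i]) || is.na(route)) next
      targets <- names(switch(route, gene = policy$geneTargets,
                              compound = policy$compoundTargets))
      rows <- manifest$mapping[
        manifest$mapping$sourceSystem == nd$xrefDb[i] &
          manifest$mapping$sourceId == nd$xrefId[i],
        c("unifiedSystem", "unifiedId"), drop = FALSE]
      if (nd$xrefDb[i] %in% names(selfMap))
        rows <- rbind(rows, data.frame(unifiedSystem = selfMap[[nd$xrefDb[i]]],
                                       unifiedId = nd$xrefId[i]))
      rows <- unique(rows[rows$unifiedSystem %in% targets, , drop = FALSE])
      total <- total + nrow(rows)
    }
  }
  total
}

bdbPredicates <- function() {
  pathwayRDF::uriTerm(pathwayRDF:::.tu(
    c("wp:bdbEntrezGene", "wp:bdbEnsembl", "wp:bdbUniprot", "wp:bdbHmdb",
      "wp:bdbChemspider")))
}
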