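#' @include sparql-parse.R
NULL

# Basic-graph-pattern evaluation by iterated hash joins over the statement
# table.  Bindings are data.frames with one column per variable (names keep
# the leading "?"), every cell an encoded RDF term.

.matchPattern <- function(stm, pat) {
  keep <- rep(TRUE, nrow(stm))
  cols <- c("subject", "predicate", "object")
  for (k in 1:3) {
    if (!startsWith(pat[k], "?")) keep <- keep & stm[[cols[k]]] == pat[k]
  }
  hit <- stm[keep, , drop = FALSE]
  if (!any(startsWith(pat, "?"))) {
    # fully concrete pattern: one empty solution if it matches, none otherwise
    return(data.frame(row.names = if (nrow(hit)) 1L else integer(0)))
  }
  out <- data.frame(row.names = seq_len(nrow(hit)))
  for (k in 1:3) {
    if (startsWith(pat[k], "?")) {
      v <- pat[k]
      if (v %in% names(out)) {
        out <- out[out[[v]] == hit[[cols[k]]][as.integer(rownames(out))], ,
                   drop = FALSE]
      } else {
        out[[v]] <- hit[[cols[k]]]
      }
    }
  }
  rownames(out) <- NULL
  out
}

.joinBindings <- function(a, b) {
  if (is.null(a)) return(b)
  if (ncol(a) == 0L) return(if (nrow(a)) b else b[0, , drop = FALSE])
  if (ncol(b) == 0L) return(if (nrow(b)) a else a[0, , drop = FALSE])
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) {
    if (nrow(a) == 0L || nrow(b) == 0L) {
      out <- cbind(a[0, , drop = FALSE], b[0, , drop = FALSE])
      return(out)
    }
    return(merge(a, b, by = NULL))
  }
  merge(a, b, by = common)
}

.applyFilter <- function(bindings, flt) {
  if (nrow(bindings) == 0L) return(bindings)
  if (!flt$var %in% names(bindings))
    stop("FILTER variable not bound in pattern: ", flt$var)
  col <- bindings[[flt$var]]
  keep <- switch(flt$type,
    regex = grepl(flt$pattern, termValue(col), ignore.case = isTRUE(flt$icase)),
    "in" = {
      inSet <- col %in% flt$values
      if (isTRUE(flt$negate)) !inSet else inSet
    },
    stop("unknown filter type: ", flt$type))
  bindings[keep, , drop = FALSE]
}

# Solve a conjunction of triple patterns (with optional filters) against a
# graph; returns the bindings table.
solveBGP <- function(graph, patterns, filters = list()) {
  stm <- graph@stm
  bindings <- NULL
  # match the most selective (fewest-solution) patterns first
  sizes <- vapply(patterns, function(p) nrow(.matchPattern(stm, p)), integer(1))
  for (i in order(sizes)) {
    bindings <- .joinBindings(bindings, .matchPattern(stm, patterns[[i]]))
    if (nrow(bindings) == 0L) break
  }
  if (is.null(bindings)) bindings <- data.frame(row.names = 1L)
  for (flt in filters) bindings <- .applyFilter(bindings, flt)
  rownames(bindings) <- NULL
  bindings
}

# Evaluate a parsed SELECT query against a graph; returns a data.frame whose
# columns are the projected variables (decoded to plain values).
evalSelect <- function(graph, q) {
  stopifnot(identical(q$form, "SELECT"))
  bindings <- solveBGP(graph, q$patterns, q$filters)
  proj <- q$projection
  if (length(proj) == 1L && identical(proj[[1]]$kind, "star"))
    proj <- lapply(names(bindings), function(v) list(kind = "var", var = v))
  aggItems <- Filter(function(it) identical(it$kind, "count"), proj)
  varItems <- Filter(function(it) identical(it$kind, "var"), proj)
  varNames <- vapply(varItems, `[[`, character(1), "var")
  missing <- setdiff(varNames, names(bindings))
  for (v in missing) bindings[[v]] <- rep(NA_character_, nrow(bindings))

  if (length(aggItems)) {
    keys <- if (length(q$groupBy)) q$groupBy else varNames
    groupId <- if (length(keys)) {
      interaction(bindings[keys], drop = TRUE, lex.order = TRUE)
    } else factor(rep(1L, nrow(bindings)))
    rows <- split(seq_len(nrow(bindings)), groupId)
    res <- data.frame(row.names = seq_along(rows))
    for (v in varNames)
      res[[v]] <- vapply(rows, function(i) bindings[[v]][i[1]], character(1))
    for (it in aggItems) {
      cnt <- vapply(rows, function(i) {
        if (it$var == "*") {
          if (it$distinct) nrow(unique(bindings[i, , drop = FALSE]))
          else length(i)
        } else {
          vals <- bindings[[it$var]][i]
          if (it$distinct) length(unique(vals)) else length(vals)
        }
      }, numeric(1))
      res[[it$alias]] <- intTerm(cnt)
    }
    order <- vapply(proj, function(it)
      if (it$kind == "var") it$var else it$alias, character(1))
    out <- res[, order, drop = FALSE]
  } else {
    out <- bindings[, varNames, drop = FALSE]
  }
  if (q$distinct) out <- unique(out)
  for (ob in rev(q$orderBy)) {
    v <- ob$var
    if (!v %in% names(out)) next
    vals <- termValue(out[[v]])
    key <- suppressWarnings(as.numeric(vals))
    if (anyNA(key)) key <- vals
    out <- out[order(key, decreasing = ob$desc), , drop = FALSE]
  }
  if (!is.na(q$limit)) out <- utils::head(out, q$limit)
  names(out) <- sub("^\\?", "", names(out))
  for (v in names(out)) out[[v]] <- termValue(out[[v]])
  rownames(out) <- NULL
  out
}
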