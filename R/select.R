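# Lipid selections: AND-combined conditions over type, leaflet and metrics.
#
# Grammar (documented; case-sensitive field names, "and" case-insensitive):
#   query     := condition ( "and" condition )*
#   condition := field op literal
#   field     := resname | leaflet | apl | thickness | neighbors
#              | inclusion_neighbors | neighbor_count[RESNAME]
#   op        := == | != | < | <= | > | >= | in
#   literal   := number | bareword | ( item , item , ... )
# Numeric operators apply only to numeric fields; `in` takes a parenthesized
# list. Example: 'resname == DPPC and apl > 0.62 and neighbor_count[DOPC] >= 2'

.SELECT_NUM_FIELDS <- c("apl", "thickness", "neighbors", "inclusion_neighbors")
.SELECT_CAT_FIELDS <- c("resname", "leaflet")

#' Parse a selection query
#'
#' @param text Query string, e.g.
#'   `"resname == DPPC and apl > 0.6"`.
#' @return A `selection_query` (list of conditions, AND-combined).
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # tokenizer with character positions (for error messages)
  pat <- paste0("\\s+|==|!=|<=|>=|<|>|\\(|\\)|,|\\[|\\]|",
                "[A-Za-z_][A-Za-z0-9_]*|[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?")
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regmatches(substr(text, pos, n),
                    regexpr(paste0("^(?:", pat, ")"), substr(text, pos, n)))
    if (length(m) == 0L || !nzchar(m))
      stop2("selection syntax error at character ", pos, ": '",
            substr(text, pos, min(n, pos + 8L)), "'")
    if (!grepl("^\\s+$", m))
      toks[[length(toks) + 1L]] <- list(tok = m, pos = pos)
    pos <- pos + nchar(m)
  }
  if (length(toks) == 0L) stop2("empty selection query")

  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]]$tok else NULL
  take <- function(expect = NULL) {
    if (i > length(toks))
      stop2("selection syntax error: unexpected end of query")
    t <- toks[[i]]
    if (!is.null(expect) && !t$tok %in% expect)
      stop2("selection syntax error at character ", t$pos, ": expected ",
            paste(sQuote(expect), collapse = " or "), ", got '", t$tok, "'")
    i <<- i + 1L
    t$tok
  }
  parse_condition <- function() {
    fpos <- toks[[i]]$pos
    field <- take()
    subfield <- NULL
    if (identical(peek(), "[")) {
      take("[")
      subfield <- take()
      take("]")
    }
    if (!is.null(subfield)) {
      if (field != "neighbor_count")
        stop2("selection error at character ", fpos,
              ": only neighbor_count[...] takes a bracket argument")
    } else if (!field %in% c(.SELECT_NUM_FIELDS, .SELECT_CAT_FIELDS)) {
      stop2("unknown selection field '", field, "' at character ", fpos)
    }
    op <- take(c("==", "!=", "<", "<=", ">", ">=", "in"))
    numeric_field <- !is.null(subfield) || field %in% .SELECT_NUM_FIELDS
    if (op == "in") {
      take("(")
      vals <- character()
      repeat {
        vals <- c(vals, take())
        if (identical(peek(), ",")) take(",") else break
      }
      take(")")
      value <- if (numeric_field) as.numeric(vals) else vals
    } else {
      if (i > length(toks))
        stop2("selection syntax error: unexpected end of query")
      vpos <- toks[[i]]$pos
      v <- take()
      if (numeric_field) {
        value <- suppressWarnings(as.numeric(v))
        if (is.na(value))
          stop2("numeric value required for field '", field,
                "' at character ", vpos)
      } else {
        if (op %in% c("<", "<=", ">", ">="))
          stop2("ordering operator '", op, "' invalid for categorical field '",
                field, "' at character ", vpos)
        value <- v
      }
    }
    list(field = field, subfield = subfield, op = op, value = value)
  }

  conditions <- list(parse_condition())
  while (!is.null(peek())) {
    kw <- take()
    if (tolower(kw) != "and")
      stop2("selection syntax error at character ", toks[[i - 1L]]$pos,
            ": expected 'and', got '", kw, "'")
    conditions[[length(conditions) + 1L]] <- parse_condition()
  }
  structure(list(conditions = conditions, text = text),
            class = "selection_query")
}

#' @export
print.selection_query <- function(x, ...) {
  cat("<selection_query>", length(x$conditions), "condition(s):", x$text, "\n")
  invisible(x)
}

.condition_mask <- function(metrics, cond, known_resnames) {
  f <- cond$field
  v <- if (!is.null(cond$subfield)) {
    if (!cond$subfield %in% known_resnames)
      stop2("unknown resname '", cond$subfield, "' in neighbor_count[...]")
    vapply(metrics$neighbor_profile, function(p)
      if (cond$subfield %in% names(p)) p[[cond$subfield]] else 0L, integer(1))
  } else switch(f,
    resname = metrics$resname,
    leaflet = as.character(metrics$leaflet),
    apl = metrics$apl,
    thickness = metrics$thickness,
    neighbors = metrics$n_neighbors,
    inclusion_neighbors = metrics$n_inclusion_neighbors,
    stop2("unknown selection field '", f, "'"))
  if (f == "resname") {
    bad <- setdiff(cond$value, known_resnames)
    if (length(bad))
      stop2("unknown resname(s) in selection: ", paste(bad, collapse = ", "))
  }
  if (f == "leaflet" && !all(cond$value %in% c("upper", "lower")))
    stop2("leaflet must be 'upper' or 'lower'")
  switch(cond$op,
         "==" = v == cond$value,
         "!=" = v != cond$value,
         "<" = v < cond$value,
         "<=" = v <= cond$value,
         ">" = v > cond$value,
         ">=" = v >= cond$value,
         "in" = v %in% cond$value)
}

#' Evaluate a selection on one frame's metrics
#'
#' Conditions are AND-combined; the result is the set of lipid ids
#' satisfying all of them for this frame. Selections are meant to be
#' re-evaluated per frame, so membership can change over time (use a fixed
#' frame's result to freeze a selection).
#'
#' @param metrics A `lipid_metrics` data frame.
#' @param query A `selection_query` or query string.
#' @param topology Optional `membrane_topology`; when given, resnames in the
#'   query are validated against it (otherwise against the metrics table).
#' @return Integer vector of selected lipid ids.
#' @export
evaluate_selection <- function(metrics, query, topology = NULL) {
  if (is.character(query)) query <- parse_query(query)
  stopifnot(inherits(query, "selection_query"))
  known <- unique(if (!is.null(topology)) topology$lipids$resname
                  else metrics$resname)
  mask <- rep(TRUE, nrow(metrics))
  for (cond in query$conditions)
    mask <- mask & .condition_mask(metrics, cond, known)
  metrics$lipid_id[mask & !is.na(mask)]
}
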