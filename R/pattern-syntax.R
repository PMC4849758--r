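# 3D pattern language: grammar, parsing, rendering, validation.
#
# A query is an alternating sequence of sequence patterns and structural
# connectors, e.g. "R-<2,6>-R-<4,5>-Y-".  Sequence patterns are PROSITE-like
# (exact letters, [allowed], {forbidden}, x wildcard); connectors carry a
# distance range in Angstroms and optionally an angle range in degrees,
# separated by "|" (both must hold).  A trailing hyphen closes the query into
# a ring: the last pattern is additionally constrained against the first.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Single-position residue specification
#'
#' One position of a sequence pattern: an exact residue, a set of allowed
#' residues, a set of forbidden residues, or a wildcard matching any residue.
#'
#' @param mode one of `"exact"`, `"allowed"`, `"forbidden"`, `"any"`.
#' @param residues character vector of one-letter amino-acid codes
#'   (empty for `mode = "any"`; exactly one for `mode = "exact"`).
#' @return an object of class `position_spec`.
#' @export
position_spec <- function(mode = c("exact", "allowed", "forbidden", "any"),
                          residues = character()) {
  mode <- match.arg(mode)
  residues <- sort(unique(toupper(residues)))
  structure(list(mode = mode, residues = residues), class = "position_spec")
}

#' Sequence pattern (contiguous run of position specifications)
#'
#' @param positions list of [position_spec()] objects, length >= 1.
#' @return an object of class `sequence_pattern`.
#' @export
sequence_pattern <- function(positions) {
  structure(list(positions = positions), class = "sequence_pattern")
}

#' Structural connector between two sequence patterns
#'
#' @param distance numeric length-2 `c(min, max)` in Angstroms, or `NULL`.
#' @param angle numeric length-2 `c(min, max)` in degrees, or `NULL`.
#'   When both are given, both must hold (conjunction).
#' @return an object of class `connector`.
#' @export
connector <- function(distance = NULL, angle = NULL) {
  structure(list(distance = distance, angle = angle), class = "connector")
}

#' 3D pattern query
#'
#' @param patterns list of [sequence_pattern()] objects (query order).
#' @param connectors list of [connector()] objects, length `length(patterns) - 1`.
#' @param cyclic logical; if `TRUE` the last pattern is additionally
#'   constrained against the first via `closing`.
#' @param closing the closing-edge [connector()] (cyclic queries only).
#'   If omitted for a cyclic query, the last connector is reused.
#' @param closing_explicit logical; whether the closing connector was written
#'   out in the query text (affects rendering only).
#' @return an object of class `query3d`.
#' @export
query3d <- function(patterns, connectors = list(), cyclic = FALSE,
                    closing = NULL, closing_explicit = FALSE) {
  if (cyclic && is.null(closing) && length(connectors) > 0) {
    closing <- connectors[[length(connectors)]]
    closing_explicit <- FALSE
  }
  structure(list(patterns = patterns, connectors = connectors,
                 cyclic = cyclic, closing = closing,
                 closing_explicit = closing_explicit),
            class = "query3d")
}

parse_error <- function(msg, span = NULL) {
  if (!is.null(span)) msg <- sprintf("%s (at '%s')", msg, span)
  stop(errorCondition(msg, class = c("motif3d_parse_error", "error")))
}

## ---- parsing ----------------------------------------------------------------

parse_pattern_element <- function(el) {
  chars <- strsplit(el, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) parse_error("empty sequence pattern", el)
  positions <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("x", "X")) {
      positions[[length(positions) + 1]] <- position_spec("any")
      i <- i + 1
    } else if (ch %in% c("[", "{")) {
      close_ch <- if (ch == "[") "]" else "}"
      j <- i + 1
      set <- character()
      while (j <= length(chars) && chars[j] != close_ch) {
        set <- c(set, chars[j])
        j <- j + 1
      }
      if (j > length(chars))
        parse_error(sprintf("unbalanced '%s'", ch), el)
      if (length(set) == 0)
        parse_error("empty bracket set", el)
      set <- toupper(set)
      bad <- setdiff(set, AA1)
      if (length(bad) > 0)
        parse_error(sprintf("unknown residue letter '%s'", bad[1]), el)
      mode <- if (ch == "[") "allowed" else "forbidden"
      positions[[length(positions) + 1]] <- position_spec(mode, set)
      i <- j + 1
    } else if (ch %in% c("]", "}")) {
      parse_error(sprintf("unbalanced '%s'", ch), el)
    } else {
      up <- toupper(ch)
      if (!up %in% AA1)
        parse_error(sprintf("unknown residue letter '%s'", ch), el)
      positions[[length(positions) + 1]] <- position_spec("exact", up)
      i <- i + 1
    }
  }
  sequence_pattern(positions)
}

parse_range <- function(txt, el) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    parse_error("range must be 'min,max'", el)
  ok <- grepl("^[0-9]+(\\.[0-9]+)?$", parts)
  if (!all(ok))
    parse_error(sprintf("invalid number '%s'", parts[!ok][1]), el)
  vals <- as.numeric(parts)
  if (vals[1] > vals[2])
    parse_error(sprintf("range min %s > max %s", parts[1], parts[2]), el)
  vals
}

parse_connector_element <- function(el) {
  if (!startsWith(el, "<") || !endsWith(el, ">"))
    parse_error("connector must be enclosed in '< >'", el)
  body <- substr(el, 2, nchar(el) - 1)
  if (nchar(body) == 0) parse_error("empty connector", el)
  pieces <- strsplit(body, "|", fixed = TRUE)[[1]]
  if (length(pieces) > 2)
    parse_error("a connector takes at most one distance and one angle range", el)
  dist <- parse_range(pieces[1], el)
  ang <- if (length(pieces) == 2) parse_range(pieces[2], el) else NULL
  connector(distance = dist, angle = ang)
}

#' Parse a 3D pattern query string
#'
#' Parses the textual pattern language into a [query3d()] object.  Sequence
#' patterns and connectors alternate, joined by hyphens; a trailing hyphen
#' marks a cyclic query.  If the trailing hyphen follows a connector, that
#' connector becomes the closing edge; if it follows a sequence pattern, the
#' last connector of the query is reused for the closure.
#'
#' @param text pattern string, e.g. `"R-<2,6>-R-<4,5>-Y-"`.  Whitespace
#'   between tokens is ignored; residue letters are case-insensitive except
#'   that `x`/`X` always denotes the wildcard.
#' @return a [query3d()] object.
#' @examples
#' q <- parse_query("R-<2,6>-R-<4,5>-Y-")
#' length(q$patterns)   # 3
#' q$cyclic             # TRUE
#' @export
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    parse_error("query must be a single character string")
  text <- gsub("[[:space:]]+", "", text)
  if (nchar(text) == 0) parse_error("empty query")

  elements <- strsplit(text, "-", fixed = TRUE)[[1]]
  cyclic <- endsWith(text, "-")
  if (cyclic) {
    # strsplit drops the trailing empty string; double-check interior blanks
  }
  if (length(elements) == 0) parse_error("empty query", text)
  if (any(elements == ""))
    parse_error("connector not flanked by patterns (empty element)", text)

  is_conn <- startsWith(elements, "<")
  n <- length(elements)

  # alternation: odd positions patterns, even positions connectors;
  # a final connector is only legal as the explicit closing edge of a cycle
  expect_conn <- (seq_len(n) %% 2) == 0
  closing <- NULL
  closing_explicit <- FALSE
  if (n > 1 && is_conn[n] && !expect_conn[n])
    parse_error("two consecutive connectors", elements[n])
  if (is_conn[n] && expect_conn[n]) {
    if (!cyclic)
      parse_error("query may not end on a connector unless cyclic", elements[n])
    closing <- parse_connector_element(elements[n])
    closing_explicit <- TRUE
    elements <- elements[-n]
    is_conn <- is_conn[-n]
    n <- n - 1
  }
  if (n == 0) parse_error("empty query", text)
  bad <- which(is_conn != ((seq_len(n) %% 2) == 0))
  if (length(bad) > 0) {
    if (is_conn[bad[1]])
      parse_error("connector not flanked by patterns", elements[bad[1]])
    parse_error("two consecutive sequence patterns (missing connector)",
                elements[bad[1]])
  }
  if (n %% 2 == 0)
    parse_error("query may not end on a connector unless cyclic",
                elements[n])

  patterns <- lapply(elements[seq(1, n, by = 2)], parse_pattern_element)
  connectors <- if (n > 1)
    lapply(elements[seq(2, n, by = 2)], parse_connector_element) else list()

  if (cyclic && is.null(closing) && length(connectors) > 0)
    closing <- connectors[[length(connectors)]]

  query3d(patterns = patterns, connectors = connectors, cyclic = cyclic,
          closing = closing, closing_explicit = closing_explicit)
}

## ---- rendering --------------------------------------------------------------

fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

render_position <- function(p) {
  switch(p$mode,
         exact = p$residues,
         any = "x",
         allowed = paste0("[", paste(p$residues, collapse = ""), "]"),
         forbidden = paste0("{", paste(p$residues, collapse = ""), "}"))
}

render_pattern <- function(sp) {
  paste(vapply(sp$positions, render_position, character(1)), collapse = "")
}

render_connector <- function(cn) {
  body <- paste0(fmt_num(cn$distance[1]), ",", fmt_num(cn$distance[2]))
  if (!is.null(cn$angle))
    body <- paste0(body, "|", fmt_num(cn$angle[1]), ",", fmt_num(cn$angle[2]))
  paste0("<", body, ">")
}

#' Render a query back to canonical pattern text
#'
#' Inverse of [parse_query()]: `parse_query(render_query(q))` is structurally
#' identical to `q`, and rendering a parsed canonical string reproduces it.
#'
#' @param q a [query3d()] object.
#' @return a single character string.
#' @export
render_query <- function(q) {
  k <- length(q$patterns)
  elems <- character(0)
  for (i in seq_len(k)) {
    elems <- c(elems, render_pattern(q$patterns[[i]]))
    if (i < k) elems <- c(elems, render_connector(q$connectors[[i]]))
  }
  if (isTRUE(q$cyclic) && isTRUE(q$closing_explicit))
    elems <- c(elems, render_connector(q$closing))
  out <- paste(elems, collapse = "-")
  if (isTRUE(q$cyclic)) out <- paste0(out, "-")
  out
}

#' @export
print.query3d <- function(x, ...) {
  cat("3D pattern query: ", render_query(x), "\n", sep = "")
  cat(sprintf("  %d sequence pattern(s), %d connector(s)%s\n",
              length(x$patterns), length(x$connectors),
              if (isTRUE(x$cyclic)) ", cyclic" else ""))
  invisible(x)
}

## ---- validation -------------------------------------------------------------

#' Validate a query against the language invariants
#'
#' Returns diagnostics rather than raising errors, so programmatically
#' constructed queries can be checked before searching.
#'
#' @param q a [query3d()] object.
#' @return character vector of diagnostic messages; empty if the query is valid.
#' @export
validate_query <- function(q) {
  diags <- character(0)
  say <- function(fmt, ...) diags <<- c(diags, sprintf(fmt, ...))

  if (length(q$patterns) < 1) say("query has no sequence patterns")
  for (i in seq_along(q$patterns)) {
    sp <- q$patterns[[i]]
    if (length(sp$positions) < 1)
      say("pattern %d has no positions", i)
    for (j in seq_along(sp$positions)) {
      p <- sp$positions[[j]]
      bad <- setdiff(p$residues, AA1)
      if (length(bad) > 0)
        say("pattern %d position %d: unknown residue '%s'", i, j, bad[1])
      if (p$mode == "exact" && length(p$residues) != 1)
        say("pattern %d position %d: exact mode needs exactly one residue", i, j)
      if (p$mode %in% c("allowed", "forbidden") && length(p$residues) < 1)
        say("pattern %d position %d: %s set is empty", i, j, p$mode)
      if (p$mode == "any" && length(p$residues) > 0)
        say("pattern %d position %d: wildcard must carry no residues", i, j)
    }
  }

  check_conn <- function(cn, label) {
    if (is.null(cn$distance) && is.null(cn$angle))
      say("%s carries no constraint", label)
    if (!is.null(cn$distance)) {
      if (cn$distance[1] < 0) say("%s: negative distance bound", label)
      if (cn$distance[1] > cn$distance[2])
        say("%s: distance min %s > max %s", label,
            fmt_num(cn$distance[1]), fmt_num(cn$distance[2]))
    }
    if (!is.null(cn$angle)) {
      if (cn$angle[1] < 0 || cn$angle[2] > 180)
        say("%s: angle range outside [0,180]", label)
      if (cn$angle[1] > cn$angle[2])
        say("%s: angle min %s > max %s", label,
            fmt_num(cn$angle[1]), fmt_num(cn$angle[2]))
    }
  }
  for (i in seq_along(q$connectors))
    check_conn(q$connectors[[i]], sprintf("connector %d", i))

  if (length(q$connectors) != max(0L, length(q$patterns) - 1L))
    say("query has %d connectors but %d patterns (need patterns - 1)",
        length(q$connectors), length(q$patterns))

  if (isTRUE(q$cyclic)) {
    if (length(q$patterns) < 2)
      say("cyclic query needs at least 2 sequence patterns")
    if (is.null(q$closing))
      say("cyclic query has no closing connector")
    else check_conn(q$closing, "closing connector")
  } else if (!is.null(q$closing)) {
    say("non-cyclic query must not carry a closing connector")
  }
  diags
}
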