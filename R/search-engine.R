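# Multi-stage structural pattern matcher:
#   1. sequence pre-filter on the extracted chain sequences,
#   2. occurrence index (every placement of every sequence pattern),
#   3. recursive backtracking over occurrence combinations with
#      structural-constraint checking and non-overlap enforcement.

#' Search configuration
#'
#' @param anchor_mode `"pseudo"` (side-chain pseudo-points) or `"CA"`
#'   (alpha carbons) for distance constraints.
#' @param same_chain_only if `TRUE`, all occurrences of a match must lie in
#'   one chain (the corpus report filter applies this too; the engine
#'   default allows cross-chain matches).
#' @param altloc_policy `"all"` (an edge passes if any conformer pair
#'   passes) or `"highest_occupancy"` (single best conformer per residue).
#' @param max_matches cap on accepted matches per structure (`Inf` for
#'   unlimited).
#' @param enumerate_all if `FALSE` (default), accepted matches claim their
#'   residues and later matches may not reuse them (greedy non-overlap, in
#'   deterministic traversal order); if `TRUE`, all satisfying assignments
#'   are returned.
#' @param prune if `FALSE`, disable early termination of failing branches
#'   (diagnostic flag; the match set is unchanged).
#' @return an object of class `search_config`.
#' @export
search_config <- function(anchor_mode = c("pseudo", "CA"),
                          same_chain_only = FALSE,
                          altloc_policy = c("all", "highest_occupancy"),
                          max_matches = Inf,
                          enumerate_all = FALSE,
                          prune = TRUE) {
  anchor_mode <- match.arg(anchor_mode)
  altloc_policy <- match.arg(altloc_policy)
  stopifnot(max_matches >= 1)
  structure(list(anchor_mode = anchor_mode,
                 same_chain_only = same_chain_only,
                 altloc_policy = altloc_policy,
                 max_matches = max_matches,
                 enumerate_all = enumerate_all,
                 prune = prune),
            class = "search_config")
}

position_matches <- function(pos, letter) {
  if (pos$mode == "any") return(TRUE)
  if (letter == "X") return(FALSE)  # nonstandard: wildcard only
  switch(pos$mode,
         exact = letter == pos$residues,
         allowed = letter %in% pos$residues,
         forbidden = !(letter %in% pos$residues))
}

pattern_occurrences <- function(sp, chain_id, sequence) {
  len <- length(sp$positions)
  n <- nchar(sequence)
  if (n < len) return(NULL)
  letters_vec <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok_mat <- vapply(sp$positions, function(pos)
    vapply(letters_vec, position_matches, logical(1), pos = pos),
    logical(n))
  ok_mat <- matrix(ok_mat, nrow = n)
  starts <- integer(0)
  for (st in 0:(n - len)) {
    if (all(ok_mat[cbind(st + seq_len(len), seq_len(len))]))
      starts <- c(starts, st)
  }
  if (length(starts) == 0) return(NULL)
  data.frame(chain = chain_id, start = starts, end = starts + len,
             stringsAsFactors = FALSE)
}

#' Build the occurrence index of a query over chain sequences
#'
#' Enumerates every placement of every sequence pattern of the query within
#' the structure's extracted sequences ("a data-structure of all available
#' sub-sequences").
#'
#' @param q a [query3d()] object.
#' @param seqs result of [chain_sequences()].
#' @return list (one element per sequence pattern, in query order) of data
#'   frames with columns `chain`, `start`, `end` (0-based, half-open).
#' @export
build_occurrence_index <- function(q, seqs) {
  lapply(q$patterns, function(sp) {
    occ <- do.call(rbind, lapply(seqs, function(cs)
      pattern_occurrences(sp, cs$chain_id, cs$sequence)))
    if (is.null(occ))
      occ <- data.frame(chain = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    # deterministic traversal order: (chain, ascending start)
    occ[order(occ$chain, occ$start), , drop = FALSE]
  })
}

occ_overlaps <- function(occ_a, occ_b) {
  occ_a$chain == occ_b$chain &&
    occ_a$start < occ_b$end && occ_b$start < occ_a$end
}

# does a pairwise non-overlapping placement of all patterns exist?
disjoint_placement_exists <- function(occ_index, i = 1, chosen = list()) {
  if (i > length(occ_index)) return(TRUE)
  occ <- occ_index[[i]]
  if (nrow(occ) == 0) return(FALSE)
  for (r in seq_len(nrow(occ))) {
    cand <- occ[r, ]
    clash <- any(vapply(chosen, occ_overlaps, logical(1), occ_b = cand))
    if (!clash &&
        disjoint_placement_exists(occ_index, i + 1, c(chosen, list(cand))))
      return(TRUE)
  }
  FALSE
}

#' Sequence pre-filter
#'
#' A candidate hit is any structure whose sequences admit a pairwise
#' non-overlapping placement of every sequence pattern of the query
#' (verified by assignment over the occurrence index, not by counting).
#'
#' @param q a [query3d()] object.
#' @param seqs result of [chain_sequences()].
#' @return `TRUE` if the structure is a candidate hit.
#' @export
prefilter <- function(q, seqs) {
  occ_index <- build_occurrence_index(q, seqs)
  if (any(vapply(occ_index, nrow, integer(1)) == 0)) return(FALSE)
  disjoint_placement_exists(occ_index)
}

# anchor of the occurrence endpoint entering a connector:
# side = "last" for the left pattern, "first" for the right pattern
occ_anchor <- function(s, occ, side, cfg) {
  idx <- if (side == "first") occ$start else occ$end - 1
  anchor_points(s, occ$chain, idx, mode = cfg$anchor_mode,
                altloc_policy = cfg$altloc_policy)
}

#' Test a structural connector between two occurrences
#'
#' Distance constraints are measured between the anchor of the last residue
#' of the left occurrence and the first residue of the right occurrence
#' (inclusive range `[min, max]`).  Angle constraints are measured between
#' the two segment vectors.  All constraints of the connector must hold;
#' under `altloc_policy = "all"` the edge passes if any conformer pair
#' passes, and the satisfying pair is recorded.
#'
#' @param cn a [connector()].
#' @param occ_a,occ_b single-row occurrence data frames (left, right).
#' @param s a `structure_index`.
#' @param cfg a [search_config()].
#' @return list with `ok` (logical), `distance`, `angle` (measured values or
#'   `NA`), `alt_a`, `alt_b` (satisfying altloc labels or `NA`).
#' @export
edge_satisfied <- function(cn, occ_a, occ_b, s, cfg = search_config()) {
  res <- list(ok = FALSE, distance = NA_real_, angle = NA_real_,
              alt_a = NA_character_, alt_b = NA_character_)
  if (!is.null(cn$angle)) {
    va <- segment_vector(s, occ_a$chain, occ_a$start, occ_a$end)
    vb <- segment_vector(s, occ_b$chain, occ_b$start, occ_b$end)
    ang <- angle_between(va, vb)
    res$angle <- ang
    if (ang < cn$angle[1] || ang > cn$angle[2]) return(res)
  }
  if (!is.null(cn$distance)) {
    pa <- occ_anchor(s, occ_a, "last", cfg)
    pb <- occ_anchor(s, occ_b, "first", cfg)
    for (i in seq_len(nrow(pa))) {
      for (j in seq_len(nrow(pb))) {
        d <- point_distance(pa[i, ], pb[j, ])
        if (d >= cn$distance[1] && d <= cn$distance[2]) {
          res$ok <- TRUE
          res$distance <- d
          res$alt_a <- rownames(pa)[i]
          res$alt_b <- rownames(pb)[j]
          return(res)
        }
      }
    }
    # record the closest miss for diagnostics
    dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                  Vectorize(function(i, j) point_distance(pa[i, ], pb[j, ])))
    res$distance <- min(dmat)
    return(res)
  }
  res$ok <- TRUE
  res
}

new_match <- function(structure_id, occs, edges) {
  structure(list(structure_id = structure_id, occurrences = occs,
                 edges = edges),
            class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  lab <- paste0(x$occurrences$chain, ":", x$occurrences$auth,
                collapse = " / ")
  cat(sprintf("match in %s: %s\n", x$structure_id, lab))
  invisible(x)
}

match_auth_labels <- function(s, occs) {
  vapply(seq_len(nrow(occs)), function(r) {
    rows <- s$chain_index[[occs$chain[r]]]
    rs <- s$residues[rows[(occs$start[r] + 1):occs$end[r]], , drop = FALSE]
    paste0(rs$one, rs$resno, rs$ins, collapse = "")
  }, character(1))
}

query_edges <- function(q) {
  k <- length(q$patterns)
  edges <- list()
  for (i in seq_len(max(0, k - 1)))
    edges[[i]] <- list(from = i, to = i + 1, cn = q$connectors[[i]])
  if (isTRUE(q$cyclic) && !is.null(q$closing) && k >= 2)
    edges[[length(edges) + 1]] <- list(from = k, to = 1, cn = q$closing)
  edges
}

#' Find all matches of a query in one structure
#'
#' Depth-first assignment of one occurrence per sequence pattern in query
#' order; after each assignment the connector to the previous pattern is
#' checked and failing branches are pruned; on assigning the final pattern
#' of a cyclic query the closing edge is also checked.  Occurrences within a
#' match must be pairwise non-overlapping.  With
#' `enumerate_all = FALSE`, accepted matches claim their residues and later
#' matches may not reuse them.  Occurrences are tried in (chain, ascending
#' index) order, so results are deterministic.
#'
#' @param q a [query3d()] object.
#' @param s a `structure_index`.
#' @param cfg a [search_config()].
#' @return list of `motif_match` objects (empty if none).
#' @export
find_matches <- function(q, s, cfg = search_config()) {
  diags <- validate_query(q)
  if (length(diags) > 0)
    stop("invalid query: ", diags[1])
  seqs <- chain_sequences(s)
  occ_index <- build_occurrence_index(q, seqs)
  if (any(vapply(occ_index, nrow, integer(1)) == 0)) return(list())
  if (!disjoint_placement_exists(occ_index)) return(list())

  k <- length(q$patterns)
  matches <- list()
  claimed <- character(0)   # "chain:index" keys of residues in accepted matches

  occ_keys <- function(occ)
    paste0(occ$chain, ":", occ$start:(occ$end - 1))

  assign_next <- function(i, chosen, edges_acc, ok_so_far) {
    if (length(matches) >= cfg$max_matches) return()
    if (i > k) {
      if (!ok_so_far) return()
      # closing edge of a cyclic query
      if (isTRUE(q$cyclic) && !is.null(q$closing) && k >= 2) {
        e <- edge_satisfied(q$closing, chosen[[k]], chosen[[1]], s, cfg)
        if (!e$ok) return()
        edges_acc[[length(edges_acc) + 1]] <-
          data.frame(from = k, to = 1, type = "closing",
                     distance = e$distance, angle = e$angle,
                     alt_from = e$alt_a, alt_to = e$alt_b,
                     stringsAsFactors = FALSE)
      }
      occs <- do.call(rbind, chosen)
      occs$pattern_index <- seq_len(k)
      occs$auth <- match_auth_labels(s, occs)
      edges_df <- if (length(edges_acc) > 0) do.call(rbind, edges_acc)
        else data.frame(from = integer(0), to = integer(0),
                        type = character(0), distance = numeric(0),
                        angle = numeric(0), alt_from = character(0),
                        alt_to = character(0), stringsAsFactors = FALSE)
      matches[[length(matches) + 1]] <<- new_match(s$id, occs, edges_df)
      if (!cfg$enumerate_all)
        claimed <<- c(claimed, unlist(lapply(chosen, occ_keys)))
      return()
    }
    occ <- occ_index[[i]]
    for (r in seq_len(nrow(occ))) {
      cand <- occ[r, , drop = FALSE]
      if (cfg$same_chain_only && i > 1 &&
          cand$chain != chosen[[1]]$chain) next
      if (!cfg$enumerate_all && any(occ_keys(cand) %in% claimed)) next
      clash <- any(vapply(chosen, occ_overlaps, logical(1), occ_b = cand))
      if (clash) next
      ok <- ok_so_far
      edges_new <- edges_acc
      if (i > 1 && ok_so_far) {
        e <- edge_satisfied(q$connectors[[i - 1]], chosen[[i - 1]], cand,
                            s, cfg)
        ok <- e$ok
        if (e$ok)
          edges_new[[length(edges_new) + 1]] <-
            data.frame(from = i - 1, to = i, type = "chain",
                       distance = e$distance, angle = e$angle,
                       alt_from = e$alt_a, alt_to = e$alt_b,
                       stringsAsFactors = FALSE)
      }
      if (cfg$prune && !ok) next  # early termination of failing branch
      assign_next(i + 1, c(chosen, list(cand)), edges_new, ok)
      if (length(matches) >= cfg$max_matches) return()
    }
  }
  assign_next(1, list(), list(), TRUE)
  matches
}

#' Search a corpus of structure files
#'
#' Loads each file (PDB or mmCIF, by extension), records the pre-filter
#' verdict, and runs [find_matches()].  Files that fail to parse are logged
#' in the report and skipped, never fatal.
#'
#' @param q a [query3d()] object.
#' @param paths character vector of structure file paths.
#' @param cfg a [search_config()].
#' @return an object of class `search_report`.
#' @export
search_corpus <- function(q, paths, cfg = search_config()) {
  entries <- lapply(paths, function(p) {
    s <- tryCatch(load_structure(p, quiet = TRUE), error = function(e) e)
    if (inherits(s, "error"))
      return(list(path = p, id = sub("\\.[^.]*$", "", basename(p)),
                  error = conditionMessage(s), prefilter = NA,
                  matches = list()))
    pf <- prefilter(q, chain_sequences(s))
    ms <- if (pf) find_matches(q, s, cfg) else list()
    list(path = p, id = s$id, error = NA_character_, prefilter = pf,
         matches = ms)
  })
  structure(list(query = render_query(q), config = cfg,
                 structures = entries,
                 n_structures = length(entries),
                 n_candidates = sum(vapply(entries, function(e)
                   isTRUE(e$prefilter), logical(1))),
                 n_matches = sum(vapply(entries, function(e)
                   length(e$matches), integer(1)))),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat(sprintf("search_report: query %s\n", x$query))
  cat(sprintf("  %d structure(s), %d candidate(s) after pre-filter, %d match(es)\n",
              x$n_structures, x$n_candidates, x$n_matches))
  for (e in x$structures) {
    if (!is.na(e$error)) {
      cat(sprintf("  %s: parse error (%s)\n", e$id, e$error))
    } else if (length(e$matches) > 0) {
      for (m in e$matches)
        cat(sprintf("  %s: %s\n", e$id,
                    paste0(m$occurrences$chain, ":", m$occurrences$auth,
                           collapse = " / ")))
    }
  }
  invisible(x)
}

match_resno_range <- function(m, s = NULL) {
  # author residue numbers are embedded in auth labels; recover numerically
  nums <- as.integer(unlist(regmatches(m$occurrences$auth,
                                       gregexpr("-?[0-9]+", m$occurrences$auth))))
  range(nums)
}

#' Filter a search report to compact single-chain motifs
#'
#' Keeps matches whose residues all lie in one chain within an
#' author-numbering span of at most `max_span` residues (the "shortest
#' regular architectures" report filter).
#'
#' @param r a `search_report`.
#' @param max_span maximum author-numbering span (inclusive residue count),
#'   default 10.
#' @param same_chain require all occurrences in one chain, default `TRUE`.
#' @return a filtered `search_report`.
#' @export
filter_report <- function(r, max_span = 10, same_chain = TRUE) {
  stopifnot(inherits(r, "search_report"))
  keep_match <- function(m) {
    one_chain <- length(unique(m$occurrences$chain)) == 1
    if (same_chain && !one_chain) return(FALSE)
    if (!one_chain) return(TRUE)  # span undefined across chains
    rng <- match_resno_range(m)
    (rng[2] - rng[1] + 1) <= max_span
  }
  r$structures <- lapply(r$structures, function(e) {
    e$matches <- Filter(keep_match, e$matches)
    e
  })
  r$n_matches <- sum(vapply(r$structures, function(e) length(e$matches),
                            integer(1)))
  r
}

report_rows <- function(r) {
  rows <- list()
  for (e in r$structures) {
    for (m in e$matches) {
      rng <- match_resno_range(m)
      rows[[length(rows) + 1]] <- data.frame(
        structure_id = e$id,
        chains = paste(unique(m$occurrences$chain), collapse = ","),
        residues = paste0("p", m$occurrences$pattern_index, ":",
                          m$occurrences$chain, ":", m$occurrences$auth,
                          collapse = ";"),
        edges = paste(vapply(seq_len(nrow(m$edges)), function(i) {
          ed <- m$edges[i, ]
          vals <- c(if (!is.na(ed$distance)) sprintf("d=%.2f", ed$distance),
                    if (!is.na(ed$angle)) sprintf("a=%.1f", ed$angle))
          sprintf("%d-%d(%s)", ed$from, ed$to, paste(vals, collapse = ","))
        }, character(1)), collapse = ";"),
        span = if (is.finite(rng[1])) rng[2] - rng[1] + 1 else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(structure_id = character(0), chains = character(0),
                      residues = character(0), edges = character(0),
                      span = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Serialize a search report
#'
#' `write_report_tsv()` writes one row per match (structure, chains,
#' per-pattern residues in author numbering, measured edge values, span).
#' `write_report_json()` mirrors the full report with provenance (query
#' text, configuration, package version).
#'
#' @param r a `search_report`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report_tsv <- function(r, path) {
  utils::write.table(report_rows(r), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(r, path) {
  payload <- list(
    query = r$query,
    config = unclass(r$config),
    package_version = as.character(utils::packageVersion("motif3d")),
    n_structures = r$n_structures,
    n_candidates = r$n_candidates,
    n_matches = r$n_matches,
    structures = lapply(r$structures, function(e) list(
      id = e$id, path = e$path, error = e$error, prefilter = e$prefilter,
      matches = lapply(e$matches, function(m) list(
        occurrences = m$occurrences, edges = m$edges)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Independently re-verify every edge of every reported match
#'
#' Post-hoc soundness checker: re-measures all connector edges (including
#' the cyclic closing edge) of every match in a report directly from the
#' structures and confirms each constraint holds.
#'
#' @param r a `search_report`.
#' @param q the [query3d()] the report was produced with.
#' @param structures named list of `structure_index` objects keyed by id
#'   (optional; by default structures are reloaded from the report paths).
#' @param cfg the [search_config()] used for the search.
#' @return `TRUE` if every edge of every match re-verifies.
#' @export
verify_report <- function(r, q, structures = NULL, cfg = search_config()) {
  edges <- query_edges(q)
  for (e in r$structures) {
    if (length(e$matches) == 0) next
    s <- if (!is.null(structures)) structures[[e$id]]
      else load_structure(e$path, quiet = TRUE)
    for (m in e$matches) {
      for (ed in edges) {
        occ_a <- m$occurrences[ed$from, , drop = FALSE]
        occ_b <- m$occurrences[ed$to, , drop = FALSE]
        chk <- edge_satisfied(ed$cn, occ_a, occ_b, s, cfg)
        if (!chk$ok) return(FALSE)
      }
      # non-overlap within the match
      for (i in seq_len(nrow(m$occurrences)))
        for (j in seq_len(nrow(m$occurrences)))
          if (i < j && occ_overlaps(m$occurrences[i, ], m$occurrences[j, ]))
            return(FALSE)
    }
  }
  TRUE
}
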