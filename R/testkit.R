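# Synthetic-structure generation and the brute-force oracle matcher.
#
# These generators are first-class, tested code: they define the study
# conditions under which the engine is validated (planted motifs recovered
# uniquely, oracle equivalence on small structures, decoy corpora).

atoms_row <- function(chain, resno, resid, elety, elesy, xyz,
                      o = 1, alt = "", ins = "") {
  data.frame(chain = chain, resno = resno, ins = ins, resid = resid,
             elety = elety, elesy = elesy,
             x = xyz[1], y = xyz[2], z = xyz[3], o = o, alt = alt,
             stringsAsFactors = FALSE)
}

aa_123 <- function(one) {
  out <- bio3d::aa123(one)
  out[is.na(out)] <- "UNK"
  out
}

#' Ideal helix structure with synthetic side-chain anchors
#'
#' Places alpha carbons on a parametric helix (angle `i * twist`, height
#' `i * rise`, radius `ca_radius`); each non-glycine residue receives a
#' single synthetic side-chain atom radially outward at
#' `sidechain_radius` from the axis so pseudo-points are well defined,
#' and backbone N and C atoms 0.7 Angstroms before/after the CA along the
#' local helix tangent so segment vectors are defined.  Defaults are
#' canonical alpha-helix values (1.5 Angstrom rise, 100 degree twist).
#'
#' @param sequence one-letter residue string.
#' @param rise rise per residue in Angstroms.
#' @param twist twist per residue in degrees.
#' @param ca_radius helix radius of the CA trace in Angstroms.
#' @param sidechain_radius radial distance of the synthetic side-chain atom
#'   from the helix axis, in Angstroms.
#' @param chain_id chain identifier.
#' @param start_resno author number of the first residue.
#' @param id structure identifier.
#' @return a `structure_index`.
#' @export
ideal_helix_structure <- function(sequence, rise = 1.5, twist = 100,
                                  ca_radius = 2.3, sidechain_radius = 5.0,
                                  chain_id = "A", start_resno = 1,
                                  id = "helix") {
  letters_vec <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  stopifnot(length(letters_vec) >= 1, rise > 0, ca_radius > 0,
            sidechain_radius > 0)
  bad <- setdiff(letters_vec, AA1)
  if (length(bad) > 0) stop("invalid residue letter '", bad[1], "'")
  omega <- twist * pi / 180
  rows <- list()
  for (i in seq_along(letters_vec)) {
    th <- (i - 1) * omega
    ca <- c(ca_radius * cos(th), ca_radius * sin(th), (i - 1) * rise)
    tangent <- c(-ca_radius * omega * sin(th), ca_radius * omega * cos(th),
                 rise)
    tangent <- tangent / sqrt(sum(tangent^2))
    resid <- aa_123(letters_vec[i])
    resno <- start_resno + i - 1
    rows[[length(rows) + 1]] <-
      atoms_row(chain_id, resno, resid, "N", "N", ca - 0.7 * tangent)
    rows[[length(rows) + 1]] <-
      atoms_row(chain_id, resno, resid, "CA", "C", ca)
    rows[[length(rows) + 1]] <-
      atoms_row(chain_id, resno, resid, "C", "C", ca + 0.7 * tangent)
    if (letters_vec[i] != "G") {
      sc <- c(sidechain_radius * cos(th), sidechain_radius * sin(th),
              (i - 1) * rise)
      rows[[length(rows) + 1]] <-
        atoms_row(chain_id, resno, resid, "CB", "C", sc)
    }
  }
  new_structure_index(do.call(rbind, rows), id = id, quiet = TRUE)
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# one representative letter per position, and the set of letters that the
# query's letter-based positions can match (for filler avoidance)
pattern_letters <- function(q) {
  used <- character(0)
  for (sp in q$patterns)
    for (p in sp$positions)
      if (p$mode %in% c("exact", "allowed")) used <- c(used, p$residues)
  unique(used)
}

position_letter <- function(p, filler) {
  switch(p$mode,
         exact = p$residues[1],
         allowed = p$residues[1],
         forbidden = setdiff(AA1, p$residues)[1],
         any = filler)
}

infeasible_error <- function(msg) {
  stop(errorCondition(msg, class = c("motif3d_infeasible", "error")))
}

# solve pattern-segment translations so that every distance edge holds
solve_anchor_layout <- function(q, dirs, lens, seed) {
  edges <- query_edges(q)
  for (e in edges) {
    if (is.null(e$cn$distance) || !is.null(e$cn$angle))
      stop("planted motifs support distance-only connectors")
    if (e$cn$distance[2] < 0.5)
      infeasible_error("distance range forces coincident anchors")
  }
  k <- length(q$patterns)
  anchor_of <- function(t_list, i, j) t_list[[i]] + j * 3.8 * dirs[[i]]
  # solve into the interior of each range so the construction survives the
  # 3-decimal coordinate rounding of PDB output
  eff_range <- function(rng) {
    m <- min(0.1, 0.25 * (rng[2] - rng[1]))
    c(rng[1] + m, rng[2] - m)
  }
  objective <- function(par) {
    t_list <- c(list(c(0, 0, 0)),
                lapply(seq_len(k - 1), function(i)
                  par[(3 * i - 2):(3 * i)]))
    viol <- 0
    for (e in edges) {
      a <- anchor_of(t_list, e$from, lens[e$from] - 1)
      b <- anchor_of(t_list, e$to, 0)
      d <- sqrt(sum((a - b)^2))
      rng <- eff_range(e$cn$distance)
      viol <- viol + max(0, rng[1] - d)^2 + max(0, d - rng[2])^2
    }
    viol
  }
  if (k == 1) return(list(list(c(0, 0, 0))))
  scale <- mean(vapply(edges, function(e) mean(e$cn$distance), numeric(1)))
  for (attempt in 1:25) {
    set.seed(seed + 7919 * attempt)
    par0 <- stats::rnorm(3 * (k - 1), sd = max(2, scale))
    fit <- stats::optim(par0, objective, method = "BFGS",
                        control = list(maxit = 500))
    if (fit$value < 1e-12) {
      t_list <- c(list(c(0, 0, 0)),
                  lapply(seq_len(k - 1), function(i)
                    fit$par[(3 * i - 2):(3 * i)]))
      return(t_list)
    }
  }
  infeasible_error("constraint set appears geometrically infeasible")
}

#' Structure with a single planted query match
#'
#' Constructs a synthetic chain in which exactly one occurrence tuple
#' satisfies every edge of the (distance-only) query, including the cyclic
#' closure.  Anchor geometry is placed by constructive solution of the
#' distance ranges; filler residues are drawn from letters the query cannot
#' match and placed far away.  Uniqueness is verified with the brute-force
#' oracle; construction is deterministic per seed.
#'
#' @param q a distance-only [query3d()].
#' @param seed integer seed.
#' @return list with elements `structure` (a `structure_index`) and
#'   `match` (the ground-truth occurrence data frame: `pattern_index`,
#'   `chain`, `start`, `end`).
#' @export
planted_motif_structure <- function(q, seed) {
  diags <- validate_query(q)
  if (length(diags) > 0) stop("invalid query: ", diags[1])
  k <- length(q$patterns)
  lens <- vapply(q$patterns, function(sp) length(sp$positions), integer(1))
  used <- pattern_letters(q)
  pool <- setdiff(c("G", "A", "S", "T", "L", "V", "I", "P", "F", "M"), used)
  if (length(pool) == 0) pool <- "A"
  filler <- pool[1]

  for (attempt in 0:19) {
    set.seed(seed + 104729 * attempt)
    dirs <- lapply(seq_len(k), function(i) random_unit())
    t_list <- solve_anchor_layout(q, dirs, lens, seed + 104729 * attempt)

    rows <- list()
    resno <- 0
    occ <- data.frame(pattern_index = integer(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
    n_filler <- 0
    add_filler <- function(n) {
      for (f in seq_len(n)) {
        resno <<- resno + 1
        n_filler <<- n_filler + 1
        base <- c(3.8 * n_filler, 500, 0)
        resid <- aa_123(filler)
        rows[[length(rows) + 1]] <<-
          atoms_row("A", resno, resid, "N", "N", base - c(0.7, 0, 0))
        rows[[length(rows) + 1]] <<-
          atoms_row("A", resno, resid, "CA", "C", base)
        rows[[length(rows) + 1]] <<-
          atoms_row("A", resno, resid, "C", "C", base + c(0.7, 0, 0))
        if (filler != "G")
          rows[[length(rows) + 1]] <<-
            atoms_row("A", resno, resid, "CB", "C", base + c(0, 0, 2))
      }
    }
    add_filler(2)
    for (i in seq_len(k)) {
      start_idx <- resno  # 0-based seq index of the next residue
      for (j in seq_len(lens[i]) - 1) {
        resno <- resno + 1
        anchor <- t_list[[i]] + j * 3.8 * dirs[[i]]
        ca <- anchor + c(0, 0, 1.5)
        letter <- position_letter(q$patterns[[i]]$positions[[j + 1]], filler)
        resid <- aa_123(letter)
        rows[[length(rows) + 1]] <-
          atoms_row("A", resno, resid, "N", "N", ca - 0.7 * dirs[[i]])
        rows[[length(rows) + 1]] <-
          atoms_row("A", resno, resid, "CA", "C", ca)
        rows[[length(rows) + 1]] <-
          atoms_row("A", resno, resid, "C", "C", ca + 0.7 * dirs[[i]])
        rows[[length(rows) + 1]] <-
          atoms_row("A", resno, resid, "CB", "C", anchor)
      }
      occ <- rbind(occ, data.frame(pattern_index = i, chain = "A",
                                   start = start_idx,
                                   end = start_idx + lens[i],
                                   stringsAsFactors = FALSE))
      if (i < k) add_filler(3)
    }
    add_filler(2)

    s <- new_structure_index(do.call(rbind, rows),
                             id = sprintf("planted_seed%d", seed),
                             quiet = TRUE)
    # uniqueness is at residue-set level: symmetric queries (equal ranges on
    # several edges) admit equivalent pattern-to-segment permutations of the
    # same residues, but no other residues may participate in any match
    oracle <- brute_force_search(q, s, search_config(enumerate_all = TRUE))
    want <- segment_set_signature(occ)
    sigs <- vapply(oracle, function(m) segment_set_signature(m$occurrences),
                   character(1))
    if (length(oracle) >= 1 && all(sigs == want))
      return(list(structure = s, match = occ))
  }
  stop("could not construct a structure with a unique planted match")
}

#' Random-coil decoy structure
#'
#' Self-avoiding random-walk CA trace (step 3.8 Angstroms, minimum
#' non-bonded separation 4 Angstroms) with synthetic single-atom side
#' chains; deterministic per seed.
#'
#' @param length number of residues (>= 1).
#' @param alphabet residue letters to draw the sequence from.
#' @param seed integer seed.
#' @param chain_id chain identifier.
#' @return a `structure_index`.
#' @export
decoy_structure <- function(length, alphabet = AA1, seed = 1,
                            chain_id = "A") {
  stopifnot(length >= 1)
  set.seed(seed)
  letters_vec <- sample(alphabet, length, replace = TRUE)
  for (restart in 1:50) {
    coords <- matrix(NA_real_, length, 3)
    coords[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in seq_len(length)[-1]) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- coords[i - 1, ] + 3.8 * random_unit()
        if (i <= 2) { coords[i, ] <- cand; placed <- TRUE; break }
        d <- sqrt(rowSums(sweep(coords[1:(i - 2), , drop = FALSE], 2,
                                cand)^2))
        if (all(d >= 4.0)) { coords[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("decoy placement failed after bounded retries")
  rows <- list()
  for (i in seq_len(length)) {
    step_dir <- if (length == 1) c(1, 0, 0)
      else if (i < length) coords[i + 1, ] - coords[i, ]
      else coords[i, ] - coords[i - 1, ]
    step_dir <- step_dir / sqrt(sum(step_dir^2))
    resid <- aa_123(letters_vec[i])
    rows[[length(rows) + 1]] <-
      atoms_row(chain_id, i, resid, "N", "N", coords[i, ] - 0.7 * step_dir)
    rows[[length(rows) + 1]] <-
      atoms_row(chain_id, i, resid, "CA", "C", coords[i, ])
    rows[[length(rows) + 1]] <-
      atoms_row(chain_id, i, resid, "C", "C", coords[i, ] + 0.7 * step_dir)
    if (letters_vec[i] != "G")
      rows[[length(rows) + 1]] <-
        atoms_row(chain_id, i, resid, "CB", "C",
                  coords[i, ] + 2.5 * random_unit())
  }
  new_structure_index(do.call(rbind, rows),
                      id = sprintf("decoy_seed%d", seed), quiet = TRUE)
}

#' Brute-force oracle matcher
#'
#' Exhaustively enumerates the Cartesian product of all occurrence tuples,
#' filters by pairwise non-overlap and by every connector edge including the
#' cyclic closure, with no pruning.  Serves as the independent oracle for
#' [find_matches()] on small structures.
#'
#' @param q a [query3d()].
#' @param s a `structure_index`.
#' @param cfg a [search_config()] (`same_chain_only` and anchor settings are
#'   honoured; enumeration is always exhaustive).
#' @param max_combinations guard on the occurrence-tuple count.
#' @return list of `motif_match` objects.
#' @export
brute_force_search <- function(q, s, cfg = search_config(enumerate_all = TRUE),
                               max_combinations = 1e6) {
  seqs <- chain_sequences(s)
  occ_index <- build_occurrence_index(q, seqs)
  counts <- vapply(occ_index, nrow, integer(1))
  if (any(counts == 0)) return(list())
  if (prod(counts) > max_combinations)
    stop("occurrence combination bound exceeded (", prod(counts), ")")
  edges <- query_edges(q)
  grid <- expand.grid(lapply(counts, seq_len))
  matches <- list()
  for (g in seq_len(nrow(grid))) {
    chosen <- lapply(seq_along(occ_index), function(i)
      occ_index[[i]][grid[g, i], , drop = FALSE])
    if (cfg$same_chain_only &&
        length(unique(vapply(chosen, `[[`, character(1), "chain"))) > 1)
      next
    clash <- FALSE
    for (i in seq_along(chosen))
      for (j in seq_along(chosen))
        if (i < j && occ_overlaps(chosen[[i]], chosen[[j]]))
          clash <- TRUE
    if (clash) next
    ok <- TRUE
    edge_rows <- list()
    for (e in edges) {
      chk <- edge_satisfied(e$cn, chosen[[e$from]], chosen[[e$to]], s, cfg)
      if (!chk$ok) { ok <- FALSE; break }
      edge_rows[[length(edge_rows) + 1]] <-
        data.frame(from = e$from, to = e$to,
                   type = if (e$to < e$from) "closing" else "chain",
                   distance = chk$distance, angle = chk$angle,
                   alt_from = chk$alt_a, alt_to = chk$alt_b,
                   stringsAsFactors = FALSE)
    }
    if (!ok) next
    occs <- do.call(rbind, chosen)
    occs$pattern_index <- seq_along(chosen)
    occs$auth <- match_auth_labels(s, occs)
    edges_df <- if (length(edge_rows) > 0) do.call(rbind, edge_rows)
      else data.frame(from = integer(0), to = integer(0), type = character(0),
                      distance = numeric(0), angle = numeric(0),
                      alt_from = character(0), alt_to = character(0),
                      stringsAsFactors = FALSE)
    matches[[length(matches) + 1]] <- new_match(s$id, occs, edges_df)
  }
  matches
}

#' Canonical signatures of a match (for set comparison)
#'
#' `match_signature()` identifies the full pattern-to-segment assignment
#' (in query order); `segment_set_signature()` identifies only the set of
#' matched residue segments, the invariant under pattern permutations of
#' symmetric queries.
#'
#' @param m a `motif_match`.
#' @param occs an occurrence data frame with `chain`, `start`, `end`.
#' @return a single string.
#' @export
match_signature <- function(m) {
  paste(sprintf("%s:%d:%d", m$occurrences$chain, m$occurrences$start,
                m$occurrences$end), collapse = "|")
}

#' @rdname match_signature
#' @export
segment_set_signature <- function(occs) {
  paste(sort(sprintf("%s:%d:%d", occs$chain, occs$start, occs$end)),
        collapse = "|")
}

#' Random grammatically valid query (for round-trip and fuzz testing)
#'
#' @param seed integer seed.
#' @param max_patterns maximum number of sequence patterns (>= 1).
#' @return a [query3d()] passing [validate_query()].
#' @export
random_query <- function(seed, max_patterns = 4) {
  stopifnot(max_patterns >= 1)
  set.seed(seed)
  k <- sample(seq_len(max_patterns), 1)
  rand_position <- function() {
    mode <- sample(c("exact", "allowed", "forbidden", "any"), 1,
                   prob = c(0.55, 0.15, 0.10, 0.20))
    n_res <- switch(mode, exact = 1, any = 0, sample(1:4, 1))
    position_spec(mode, if (n_res > 0) sample(AA1, n_res) else character())
  }
  rand_pattern <- function()
    sequence_pattern(lapply(seq_len(sample(1:3, 1)), function(i)
      rand_position()))
  rand_connector <- function() {
    lo <- sample(0:12, 1)
    hi <- lo + sample(1:6, 1)
    ang <- NULL
    if (stats::runif(1) < 0.3) {
      alo <- sample(0:120, 1)
      ahi <- min(180, alo + sample(0:60, 1))
      ang <- c(alo, ahi)
    }
    connector(distance = c(lo, hi), angle = ang)
  }
  patterns <- lapply(seq_len(k), function(i) rand_pattern())
  connectors <- if (k > 1)
    lapply(seq_len(k - 1), function(i) rand_connector()) else list()
  cyclic <- k >= 2 && stats::runif(1) < 0.3
  closing <- NULL
  closing_explicit <- FALSE
  if (cyclic && stats::runif(1) < 0.5) {
    closing <- rand_connector()
    closing_explicit <- TRUE
  }
  query3d(patterns, connectors, cyclic = cyclic, closing = closing,
          closing_explicit = closing_explicit)
}

## ---- fixture output ---------------------------------------------------------

#' Write a structure to a PDB or minimal mmCIF file
#'
#' `write_structure_pdb()` emits standard ATOM records (via bio3d);
#' `write_structure_cif()` emits a minimal `atom_site` loop.  Both are used
#' to materialize synthetic structures as text fixtures and by the
#' `make-fixture` command.
#'
#' @param s a `structure_index`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  at <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno,
                   resid = at$resid,
                   elety = at$elety,
                   chain = at$chain,
                   insert = ifelse(at$ins == "", NA, at$ins),
                   alt = ifelse(at$alt == "", NA, at$alt),
                   o = at$o,
                   b = rep(0, nrow(at)),
                   elesy = at$elesy)
  invisible(path)
}

#' @rdname write_structure_pdb
#' @export
write_structure_cif <- function(s, path) {
  at <- s$atoms
  hdr <- c(sprintf("data_%s", gsub("[^A-Za-z0-9_]", "_", s$id)),
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  body <- sprintf(
    "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
    seq_len(nrow(at)), at$elesy, at$elety,
    ifelse(at$alt == "", ".", at$alt),
    at$resid, at$chain, at$resno,
    ifelse(at$ins == "", "?", at$ins),
    at$x, at$y, at$z, at$o,
    at$resno, at$resid, at$chain, at$elety)
  writeLines(c(hdr, body), path)
  invisible(path)
}
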