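worked_q <- parse_query(IL10R1_QUERY)

seqs_of <- function(seq_strings) {
  # minimal chain_sequences-shaped input for sequence-level operations
  out <- lapply(seq_along(seq_strings), function(i) {
    list(chain_id = names(seq_strings)[i], sequence = seq_strings[[i]],
         map = NULL)
  })
  names(out) <- names(seq_strings)
  out
}

test_that("the occurrence index enumerates every placement", {
  occ <- build_occurrence_index(worked_q, seqs_of(c(A = "RYRER")))
  expect_equal(occ[[1]]$start, c(0, 2, 4))  # R placements
  expect_equal(occ[[2]]$start, c(0, 2, 4))
  expect_equal(occ[[3]]$start, 1)           # Y placement
  # multi-position pattern with wildcard and forbidden set
  q2 <- parse_query("[RK]x{P}")
  occ2 <- build_occurrence_index(q2, seqs_of(c(A = "RAPKGAKPP")))
  # R@0:RAP has P at forbidden position -> rejected; K@3:KGA ok; K@6:KPP no
  expect_equal(occ2[[1]]$start, 3)
})

test_that("the pre-filter demands a non-overlapping placement of all patterns", {
  expect_true(prefilter(worked_q, seqs_of(c(A = "RYR"))))
  expect_false(prefilter(worked_q, seqs_of(c(A = "RYA"))))
  expect_true(prefilter(worked_q, seqs_of(c(A = "RRAAAY"))))
  # counting alone would pass this, a placement check must not:
  # pattern "RY" and pattern "Y" on "RY" share the only Y
  q <- parse_query("RY-<2,6>-Y")
  expect_false(prefilter(q, seqs_of(c(A = "RY"))))
  expect_true(prefilter(q, seqs_of(c(A = "RYY"))))
  # placements may straddle chains
  expect_true(prefilter(worked_q, seqs_of(c(A = "RY", B = "R"))))
})

test_that("edge ranges are inclusive on both ends", {
  at <- rbind(fx_ala("A", 1, ca = c(0, 0, 0), cb = c(0, 0, 0)),
              fx_ala("A", 2, ca = c(4.5, 0, 0), cb = c(4.5, 0, 0)))
  s <- fx_structure(at)
  occ_a <- data.frame(chain = "A", start = 0L, end = 1L)
  occ_b <- data.frame(chain = "A", start = 1L, end = 2L)
  cfg <- search_config()
  expect_true(edge_satisfied(connector(c(4, 5)), occ_a, occ_b, s, cfg)$ok)
  expect_true(edge_satisfied(connector(c(4.5, 4.5)), occ_a, occ_b, s, cfg)$ok)
  expect_false(edge_satisfied(connector(c(2, 4)), occ_a, occ_b, s, cfg)$ok)
  expect_false(edge_satisfied(connector(c(4.6, 9)), occ_a, occ_b, s, cfg)$ok)
})

test_that("an altloc pair can satisfy an edge under policy=all but not under best-occupancy", {
  # conformer B of residue 1 is 4.5 A from residue 2; conformer A is 12 A away
  at <- rbind(fx_arg_two_conformers("A", 1, cb_a = c(-10, 0, 0),
                                    cb_b = c(-2.5, 0, 0)),
              fx_ala("A", 2, ca = c(2, 0, 0), cb = c(2, 0, 0)))
  at$o[at$alt == "A"] <- 0.6  # make conformer A the best-occupied one
  s <- fx_structure(at)
  occ_a <- data.frame(chain = "A", start = 0L, end = 1L)
  occ_b <- data.frame(chain = "A", start = 1L, end = 2L)
  e <- edge_satisfied(connector(c(4, 5)), occ_a, occ_b, s, search_config())
  expect_true(e$ok)
  expect_equal(e$alt_a, "B")
  expect_equal(e$distance, 4.5)
  e2 <- edge_satisfied(connector(c(4, 5)), occ_a, occ_b, s,
                       search_config(altloc_policy = "highest_occupancy"))
  expect_false(e2$ok)
})

test_that("angle constraints are measured between segment vectors", {
  # two 2-residue segments with perpendicular CA directions
  at <- rbind(fx_ala("A", 1, ca = c(0, 0, 0), cb = c(0, 0, 1)),
              fx_ala("A", 2, ca = c(3.8, 0, 0), cb = c(3.8, 0, 1)),
              fx_ala("A", 3, ca = c(10, 0, 0), cb = c(10, 0, 1)),
              fx_ala("A", 4, ca = c(10, 3.8, 0), cb = c(10, 3.8, 1)))
  s <- fx_structure(at)
  occ_a <- data.frame(chain = "A", start = 0L, end = 2L)
  occ_b <- data.frame(chain = "A", start = 2L, end = 4L)
  cn <- connector(c(0, 50), angle = c(80, 100))
  e <- edge_satisfied(cn, occ_a, occ_b, s, search_config())
  expect_true(e$ok)
  expect_equal(e$angle, 90, tolerance = 1e-9)
  cn2 <- connector(c(0, 50), angle = c(0, 45))
  expect_false(edge_satisfied(cn2, occ_a, occ_b, s, search_config())$ok)
})

test_that("find_matches recovers the planted motif and honours the cyclic closure", {
  pm <- planted_motif_structure(worked_q, seed = 11)
  m <- find_matches(worked_q, pm$structure, search_config())
  expect_length(m, 1)
  expect_identical(segment_set_signature(m[[1]]$occurrences),
                   segment_set_signature(pm$match))
  # all three edges (two connectors + closure) recorded and within range
  expect_equal(nrow(m[[1]]$edges), 3)
  expect_true(any(m[[1]]$edges$type == "closing"))
  d <- m[[1]]$edges$distance
  expect_true(d[1] >= 2 && d[1] <= 6)
  expect_true(all(d[2:3] >= 4 & d[2:3] <= 5))
})

test_that("a synthetic helical motif numbered like the 2ACA hit is matched at R155/R151/Y152", {
  s <- fx_synthetic_2aca_like()
  expect_identical(chain_sequences(s)$A$sequence, "AARYRERAA")
  m <- find_matches(worked_q, s, search_config())
  expect_length(m, 1)
  auth <- sort(m[[1]]$occurrences$auth)
  expect_identical(auth, sort(c("R155", "R151", "Y152")))
})

test_that("structures failing the pre-filter yield no matches cheaply", {
  s <- ideal_helix_structure("AAAA")
  expect_false(prefilter(worked_q, chain_sequences(s)))
  expect_length(find_matches(worked_q, s, search_config()), 0)
})

test_that("greedy acceptance never reuses residues; enumerate_all returns every assignment", {
  # two disjoint planted motifs merged into one two-chain structure
  pm1 <- planted_motif_structure(worked_q, seed = 21)
  pm2 <- planted_motif_structure(worked_q, seed = 22)
  at2 <- pm2$structure$atoms
  at2$chain <- "B"
  at2[, c("x", "y", "z")] <- at2[, c("x", "y", "z")] + 300
  s <- fx_structure(rbind(pm1$structure$atoms, at2), id = "double")
  greedy <- find_matches(worked_q, s, search_config())
  expect_length(greedy, 2)
  used <- unlist(lapply(greedy, function(m)
    paste0(m$occurrences$chain, ":", m$occurrences$start)))
  expect_false(any(duplicated(used)))
  all_m <- find_matches(worked_q, s, search_config(enumerate_all = TRUE))
  # each motif admits the symmetric R-swap, so 2 assignments per site
  expect_gte(length(all_m), 4)
  # residue-level non-overlap also holds within every match
  for (m in all_m) {
    segs <- m$occurrences
    for (i in seq_len(nrow(segs)))
      for (j in seq_len(nrow(segs)))
        if (i < j)
          expect_false(segs$chain[i] == segs$chain[j] &&
                         segs$start[i] < segs$end[j] &&
                         segs$start[j] < segs$end[i])
  }
})

test_that("disabling branch pruning does not change the match set", {
  for (seed in c(31, 32, 33)) {
    d <- decoy_structure(45, alphabet = c("R", "Y", "A", "G", "L", "E"),
                         seed = seed)
    pruned <- find_matches(worked_q, d, search_config(enumerate_all = TRUE))
    full <- find_matches(worked_q, d,
                         search_config(enumerate_all = TRUE, prune = FALSE))
    expect_identical(engine_signatures(pruned), engine_signatures(full))
  }
})

test_that("same_chain_only restricts assignments to a single chain", {
  pm <- planted_motif_structure(worked_q, seed = 41)
  # move the tyrosine pattern's chain id to B: cross-chain match survives
  # only without same_chain_only
  at <- pm$structure$atoms
  y_res <- pm$match$start[3]
  cs <- chain_sequences(pm$structure)$A$map
  y_resno <- cs$resno[cs$seq_index == y_res]
  at$chain[at$resno == y_resno] <- "B"
  s <- fx_structure(at, id = "split")
  cross <- find_matches(worked_q, s, search_config())
  expect_length(cross, 1)
  expect_setequal(unique(cross[[1]]$occurrences$chain), c("A", "B"))
  same <- find_matches(worked_q, s, search_config(same_chain_only = TRUE))
  expect_length(same, 0)
})

test_that("corpus search logs parse failures and serializes deterministically", {
  dir <- withr::local_tempdir()
  pm <- planted_motif_structure(worked_q, seed = 51)
  p1 <- file.path(dir, "hit.pdb")
  write_structure_pdb(pm$structure, p1)
  p2 <- file.path(dir, "miss.pdb")
  write_structure_pdb(ideal_helix_structure("AAAAGGLL"), p2)
  p3 <- file.path(dir, "broken.pdb")
  writeLines("not a structure", p3)

  r <- search_corpus(worked_q, c(p1, p2, p3), search_config())
  expect_equal(r$n_structures, 3)
  expect_equal(r$n_matches, 1)
  errs <- vapply(r$structures, function(e) !is.na(e$error), logical(1))
  expect_equal(sum(errs), 1)

  t1 <- file.path(dir, "r1.tsv"); t2 <- file.path(dir, "r2.tsv")
  write_report_tsv(r, t1)
  r_again <- search_corpus(worked_q, c(p1, p2, p3), search_config())
  write_report_tsv(r_again, t2)
  expect_identical(readLines(t1), readLines(t2))

  j <- file.path(dir, "r.json")
  write_report_json(r, j)
  parsed <- jsonlite::read_json(j)
  expect_identical(parsed$query, IL10R1_QUERY)
  expect_equal(parsed$n_matches, 1)
  expect_true(!is.null(parsed$package_version))
})

test_that("the span filter keeps compact single-chain motifs only", {
  # compact: synthetic helical motif spanning authors 151-155 (span 5)
  s <- fx_synthetic_2aca_like()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "compact.pdb")
  write_structure_pdb(s, p)
  r <- search_corpus(worked_q, p, search_config())
  expect_equal(filter_report(r, max_span = 10)$n_matches, 1)
  expect_equal(filter_report(r, max_span = 4)$n_matches, 0)

  # a cross-chain match is removed when same_chain filtering is on
  pm <- planted_motif_structure(worked_q, seed = 61)
  at <- pm$structure$atoms
  cs <- chain_sequences(pm$structure)$A$map
  y_resno <- cs$resno[cs$seq_index == pm$match$start[3]]
  at$chain[at$resno == y_resno] <- "B"
  p2 <- file.path(dir, "cross.pdb")
  write_structure_pdb(fx_structure(at, id = "cross"), p2)
  r2 <- search_corpus(worked_q, p2, search_config())
  expect_equal(r2$n_matches, 1)
  expect_equal(filter_report(r2, same_chain = TRUE)$n_matches, 0)
  expect_equal(filter_report(r2, same_chain = FALSE)$n_matches, 1)
})

test_that("every reported match re-verifies independently", {
  dir <- withr::local_tempdir()
  paths <- character(0)
  for (seed in 71:78) {
    d <- decoy_structure(40, alphabet = c("R", "Y", "A", "G"), seed = seed)
    p <- file.path(dir, sprintf("d%d.pdb", seed))
    write_structure_pdb(d, p)
    paths <- c(paths, p)
  }
  r <- search_corpus(worked_q, paths, search_config())
  expect_true(verify_report(r, worked_q, cfg = search_config()))
})
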