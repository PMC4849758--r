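# Shared fixtures, all generated in code.

# the worked cyclic query: two arginines 2-6 A apart, a tyrosine 4-5 A from
# the second and (by cyclic closure) from the first
IL10R1_QUERY <- "R-<2,6>-R-<4,5>-Y-"

# atoms-row helper mirroring the package-internal layout
fx_atom <- function(chain, resno, resid, elety, elesy, x, y, z,
                    o = 1, alt = "", ins = "") {
  data.frame(chain = chain, resno = resno, ins = ins, resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z,
             o = o, alt = alt, stringsAsFactors = FALSE)
}

fx_structure <- function(atoms, id = "fixture") {
  motif3d:::new_structure_index(atoms, id = id, quiet = TRUE)
}

# one Ala residue with backbone plus CB at a known location
fx_ala <- function(chain = "A", resno = 1, cb = c(2, 0, 0),
                   ca = c(0, 0, 0)) {
  rbind(
    fx_atom(chain, resno, "ALA", "N", "N", ca[1] - 1.4, ca[2], ca[3]),
    fx_atom(chain, resno, "ALA", "CA", "C", ca[1], ca[2], ca[3]),
    fx_atom(chain, resno, "ALA", "C", "C", ca[1] + 1.4, ca[2], ca[3]),
    fx_atom(chain, resno, "ALA", "CB", "C", cb[1], cb[2], cb[3]))
}

# an arginine with two side-chain conformers (altloc A/B) of equal occupancy
fx_arg_two_conformers <- function(chain = "A", resno = 1,
                                  cb_a = c(2, 0, 0), cb_b = c(-2, 0, 0)) {
  rbind(
    fx_atom(chain, resno, "ARG", "N", "N", -1.4, 0, 0),
    fx_atom(chain, resno, "ARG", "CA", "C", 0, 0, 0),
    fx_atom(chain, resno, "ARG", "C", "C", 1.4, 0, 0),
    fx_atom(chain, resno, "ARG", "CB", "C", cb_a[1], cb_a[2], cb_a[3],
            o = 0.5, alt = "A"),
    fx_atom(chain, resno, "ARG", "CB", "C", cb_b[1], cb_b[2], cb_b[3],
            o = 0.5, alt = "B"))
}

# a synthetic helix stand-in for the 2ACA 151-RYRER-155 structural motif:
# ideal helix numbered from 149 so the motif occupies author residues
# 151-155, with the side-chain anchors of R151, Y152 and R155 leaning
# together (as rotamers do in real helical motifs) so that the pairwise
# pseudo-point distances satisfy the worked query.  Synthetic geometry,
# not the crystal structure.
fx_synthetic_2aca_like <- function() {
  h <- ideal_helix_structure("AARYRERAA", start_resno = 149,
                             id = "synthetic_2aca_like")
  at <- h$atoms
  ca <- function(resno) {
    r <- at[at$resno == resno & at$elety == "CA", ]
    c(r$x, r$y, r$z)
  }
  cent <- (ca(151) + ca(152) + ca(155)) / 3
  # anchor cluster: R155-R151 4.0 A, Y152 4.5 A from each arginine
  cluster <- rbind(p155 = c(0, 0, 0), p151 = c(4, 0, 0),
                   p152 = c(2, sqrt(4.5^2 - 2^2), 0))
  cluster <- sweep(cluster, 2, colMeans(cluster))
  cluster <- sweep(cluster, 2, cent, `+`)
  for (nm in c("p155", "p151", "p152")) {
    resno <- as.integer(sub("p", "", nm))
    sel <- at$resno == resno & at$elety == "CB"
    at[sel, c("x", "y", "z")] <- as.list(cluster[nm, ])
  }
  fx_structure(at, id = "synthetic_2aca_like")
}

engine_signatures <- function(matches)
  sort(vapply(matches, match_signature, character(1)))

# location of optional user-fetched real PDB entries (scripts/fetch_structures.R)
real_pdb_path <- function(id) {
  p <- system.file("extdata", "pdb", paste0(tolower(id), ".pdb"),
                   package = "motif3d")
  if (nzchar(p)) return(p)
  file.path(testthat::test_path("..", "..", "inst", "extdata", "pdb"),
            paste0(tolower(id), ".pdb"))
}
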