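# Solvent-accessible surface area (Shrake-Rupley sphere sampling) and the
# buried-surface-area utility for protein-protein interfaces.

# Chothia-style van der Waals radii (Angstroms), keyed on element with a
# special case for the backbone carbonyl carbon (atom name "C").
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80)
VDW_DEFAULT <- 1.80
VDW_CARBONYL_C <- 1.76

atom_radii <- function(elety, elesy) {
  r <- unname(VDW_RADII[elesy])
  r[is.na(r)] <- VDW_DEFAULT
  r[elety == "C" & elesy == "C"] <- VDW_CARBONYL_C
  r
}

# deterministic quasi-uniform points on the unit sphere (golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples `n_points` quasi-uniform test points on each atom's solvent
#' sphere (radius + probe) and counts the fraction not buried inside any
#' neighbouring atom's solvent sphere.
#'
#' @param coords numeric matrix (n x 3) of atom centres in Angstroms.
#' @param radii numeric vector of van der Waals radii (Angstroms).
#' @param probe probe radius in Angstroms (water: 1.4).
#' @param n_points number of sphere sample points per atom.
#' @return numeric vector of per-atom accessible areas in square Angstroms.
#' @export
shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(radii) == n, n >= 1)
  pts <- sphere_points(n_points)
  rs <- radii + probe
  area <- numeric(n)
  # pairwise neighbour lists under the maximal interaction cutoff
  maxr <- max(rs)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * rs[i]^2
      next
    }
    p <- sweep(pts * rs[i], 2, coords[i, ], `+`)  # test points on sphere i
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(p[free, , drop = FALSE], 2, coords[j, ])^2)
      free[free] <- dj >= rs[j]^2
    }
    area[i] <- 4 * pi * rs[i]^2 * sum(free) / n_points
  }
  area
}

structure_sasa_atoms <- function(s, chains) {
  at <- s$atoms
  keep <- at$chain %in% chains & !(at$elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  # for alternate conformations keep the highest-occupancy copy of each atom
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")
    ord <- order(key, -at$o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$ins, at$elety,
                               sep = "\r")), , drop = FALSE]
  }
  at
}

#' Buried surface area between two chain groups
#'
#' Computes `(SASA(A) + SASA(B) - SASA(A+B)) / 2` with the Shrake-Rupley
#' method, a fixed Chothia-style radii table, and hydrogens excluded.  This
#' is the conventional per-side buried interface area (the quantity usually
#' quoted for protein-protein complexes, e.g. a few hundred square Angstroms
#' for a cytokine-receptor interface).
#'
#' @param s a `structure_index` containing both groups.
#' @param group_A,group_B disjoint, non-empty character vectors of chain ids.
#' @param probe probe radius in Angstroms, default 1.4.
#' @param n_points sphere sample points per atom, default 960.
#' @return buried area in square Angstroms.
#' @export
buried_area <- function(s, group_A, group_B, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "structure_index"))
  if (length(group_A) == 0 || length(group_B) == 0)
    stop("both chain groups must be non-empty")
  if (length(intersect(group_A, group_B)) > 0)
    stop("chain groups overlap: ", paste(intersect(group_A, group_B),
                                         collapse = ","))
  missing <- setdiff(c(group_A, group_B), names(s$chain_index))
  if (length(missing) > 0)
    stop("chain(s) not in structure: ", paste(missing, collapse = ","))
  a <- structure_sasa_atoms(s, group_A)
  b <- structure_sasa_atoms(s, group_B)
  ra <- atom_radii(a$elety, a$elesy)
  rb <- atom_radii(b$elety, b$elesy)
  xyz <- c("x", "y", "z")
  sa <- sum(shrake_rupley(as.matrix(a[, xyz]), ra, probe, n_points))
  sb <- sum(shrake_rupley(as.matrix(b[, xyz]), rb, probe, n_points))
  sab <- sum(shrake_rupley(rbind(as.matrix(a[, xyz]), as.matrix(b[, xyz])),
                           c(ra, rb), probe, n_points))
  (sa + sb - sab) / 2
}
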