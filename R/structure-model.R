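# Structure ingestion and geometric primitives.
#
# A structure_index holds one model of one structure: the polymer atoms, a
# per-chain residue table with extracted one-letter sequences, and
# precomputed per-residue anchor points (alpha-carbon and side-chain
# pseudo-point, one per alternate-location conformer).

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

guess_element <- function(elety) {
  s <- gsub("[0-9']", "", elety)
  toupper(substr(s, 1, 1))
}

# anchors for one residue's atom block: one row per altloc conformer
residue_anchors <- function(ra) {
  alts <- sort(unique(ra$alt[ra$alt != ""]))
  if (length(alts) == 0) alts <- ""
  k <- length(alts)
  ca <- matrix(NA_real_, k, 3)
  pseudo <- matrix(NA_real_, k, 3)
  occ <- rep(1, k)
  fallback <- FALSE
  side <- !(ra$elety %in% BACKBONE_ATOMS) & !(ra$elesy %in% c("H", "D"))
  for (i in seq_len(k)) {
    grp <- ra$alt == "" | ra$alt == alts[i]
    ca_rows <- which(grp & ra$elety == "CA")
    if (length(ca_rows) == 0) ca_rows <- which(ra$elety == "CA")
    ca[i, ] <- as.numeric(ra[ca_rows[1], c("x", "y", "z")])
    sc <- which(grp & side)
    if (length(sc) > 0) {
      pseudo[i, ] <- colMeans(ra[sc, c("x", "y", "z"), drop = FALSE])
    } else {
      pseudo[i, ] <- ca[i, ]
      fallback <- TRUE
    }
    own <- which(ra$alt == alts[i])
    if (length(own) > 0) occ[i] <- mean(ra$o[own], na.rm = TRUE)
  }
  pick_bb <- function(name) {
    rows <- which(ra$elety == name)
    if (length(rows) == 0) return(NULL)
    rows <- rows[which.max(ra$o[rows])]
    as.numeric(ra[rows, c("x", "y", "z")])
  }
  list(alt = alts, ca = ca, pseudo = pseudo, occ = occ,
       N = pick_bb("N"), C = pick_bb("C"), fallback = fallback)
}

# atoms: data.frame(chain, resno, ins, resid, elety, elesy, x, y, z, o, alt)
new_structure_index <- function(atoms, id = "structure", model = 1L,
                                quiet = FALSE) {
  stopifnot(is.data.frame(atoms))
  keep <- is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0)
    stop("no polymer residues in '", id, "'")
  atoms$key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  res_keys <- unique(atoms$key)

  blocks <- split(seq_len(nrow(atoms)), factor(atoms$key, levels = res_keys))
  has_ca <- vapply(blocks, function(idx) any(atoms$elety[idx] == "CA"),
                   logical(1))
  blocks <- blocks[has_ca]
  if (length(blocks) == 0)
    stop("no polymer residues in '", id, "' (no residue has a CA atom)")

  first <- vapply(blocks, `[`, integer(1), 1)
  residues <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    ins = atoms$ins[first],
    resid = atoms$resid[first],
    stringsAsFactors = FALSE)
  residues$one <- suppressWarnings(bio3d::aa321(residues$resid))
  residues$one[is.na(residues$one)] <- "X"
  residues$seq_index <- stats::ave(seq_len(nrow(residues)), residues$chain,
                                   FUN = seq_along) - 1L

  anchors <- lapply(blocks, function(idx)
    residue_anchors(atoms[idx, , drop = FALSE]))
  n_fb <- sum(vapply(anchors, `[[`, logical(1), "fallback") &
                residues$resid != "GLY")
  if (n_fb > 0 && !quiet)
    warning(sprintf(
      "%s: %d non-glycine residue(s) without resolved side-chain atoms; pseudo-point falls back to CA",
      id, n_fb), call. = FALSE)

  chains <- unique(residues$chain)
  by_chain <- lapply(chains, function(ch) which(residues$chain == ch))
  names(by_chain) <- chains

  atoms$key <- NULL
  structure(list(id = id, model = as.integer(model), atoms = atoms,
                 residues = residues, anchors = anchors,
                 chain_index = by_chain),
            class = "structure_index")
}

#' @export
print.structure_index <- function(x, ...) {
  cat(sprintf("structure_index '%s' (model %d): %d atoms, %d residues, chains %s\n",
              x$id, x$model, nrow(x$atoms), nrow(x$residues),
              paste(names(x$chain_index), collapse = ",")))
  invisible(x)
}

#' Load a protein structure from a PDB or mmCIF file
#'
#' Parses the coordinate file (via bio3d), keeps one model, drops HETATM
#' (non-polymer) records and residues lacking an alpha carbon, extracts
#' per-chain one-letter sequences with the author residue numbering, and
#' precomputes anchor points (CA and side-chain pseudo-point per alternate
#' conformer) for every residue.
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param model model number to index (multi-model PDB input), default 1.
#' @param quiet suppress the pseudo-point fallback warning.
#' @return an object of class `structure_index`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = 1, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = model > 1, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  at <- pdb$atom
  xyz <- c("x", "y", "z")
  if (model > 1) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model)
      stop(sprintf("model %d absent from '%s'", model, path))
    at[, xyz] <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer residues in '", path, "'")
  elesy <- at$elesy
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- guess_element(at$elety[miss])
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    elesy = toupper(elesy),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)
  id <- sub("\\.[^.]*$", "", basename(path))
  new_structure_index(atoms, id = id, model = model, quiet = quiet)
}

#' Extract per-chain one-letter sequences with author numbering
#'
#' @param s a `structure_index`.
#' @return a named list (one entry per chain) of lists with elements
#'   `chain_id`, `sequence` (one-letter string, `X` for nonstandard
#'   residues), and `map`, a data frame mapping 0-based `seq_index` to the
#'   author `resno`, insertion code and combined `auth` label.
#' @export
chain_sequences <- function(s) {
  stopifnot(inherits(s, "structure_index"))
  out <- lapply(names(s$chain_index), function(ch) {
    rows <- s$chain_index[[ch]]
    rs <- s$residues[rows, , drop = FALSE]
    list(chain_id = ch,
         sequence = paste(rs$one, collapse = ""),
         map = data.frame(seq_index = rs$seq_index, resno = rs$resno,
                          ins = rs$ins,
                          auth = paste0(rs$resno, rs$ins),
                          one = rs$one,
                          stringsAsFactors = FALSE))
  })
  names(out) <- names(s$chain_index)
  out
}

residue_row <- function(s, chain, seq_index) {
  rows <- s$chain_index[[chain]]
  if (is.null(rows)) stop("no chain '", chain, "' in structure '", s$id, "'")
  if (seq_index < 0 || seq_index >= length(rows))
    stop(sprintf("seq_index %d out of range for chain %s", seq_index, chain))
  rows[seq_index + 1]
}

#' Anchor points of a residue
#'
#' `mode = "CA"` returns the alpha-carbon coordinate(s); `mode = "pseudo"`
#' returns the unweighted centroid of the side-chain heavy atoms (all
#' non-hydrogen atoms excluding backbone N, CA, C, O, OXT).  Glycine and
#' residues with no resolved side-chain atoms fall back to the CA.  One
#' anchor is returned per alternate-location conformer under
#' `altloc_policy = "all"`; `"highest_occupancy"` keeps the single
#' best-occupied conformer.
#'
#' @param s a `structure_index`.
#' @param chain chain identifier.
#' @param seq_index 0-based residue index within the chain.
#' @param mode `"pseudo"` or `"CA"`.
#' @param altloc_policy `"all"` or `"highest_occupancy"`.
#' @return numeric matrix (one anchor per row, columns x/y/z) with the
#'   altloc labels as row names.
#' @export
anchor_points <- function(s, chain, seq_index, mode = c("pseudo", "CA"),
                          altloc_policy = c("all", "highest_occupancy")) {
  mode <- match.arg(mode)
  altloc_policy <- match.arg(altloc_policy)
  an <- s$anchors[[residue_row(s, chain, seq_index)]]
  m <- if (mode == "CA") an$ca else an$pseudo
  rownames(m) <- an$alt
  if (altloc_policy == "highest_occupancy" && nrow(m) > 1)
    m <- m[which.max(an$occ), , drop = FALSE]
  m
}

#' Euclidean distance between two points (Angstroms)
#'
#' @param a,b numeric 3-vectors.
#' @return the Euclidean norm of `a - b`.
#' @export
point_distance <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Direction vector of a matched segment
#'
#' For segments of two or more residues: the unit vector from the CA of the
#' first residue to the CA of the last.  For single-residue segments: the
#' unit vector from the residue's backbone N to its backbone C.  Used for
#' inter-segment angle constraints.
#'
#' @param s a `structure_index`.
#' @param chain chain identifier.
#' @param start,end half-open 0-based residue index range `[start, end)`.
#' @return unit numeric 3-vector.
#' @export
segment_vector <- function(s, chain, start, end) {
  len <- end - start
  if (len < 1) stop("segment must contain at least one residue")
  if (len == 1) {
    an <- s$anchors[[residue_row(s, chain, start)]]
    if (is.null(an$N) || is.null(an$C)) {
      rs <- s$residues[residue_row(s, chain, start), ]
      stop(sprintf("residue %s%s (chain %s) lacks backbone N/C atoms",
                   rs$resno, rs$ins, chain))
    }
    v <- an$C - an$N
  } else {
    ca1 <- anchor_points(s, chain, start, "CA", "highest_occupancy")
    ca2 <- anchor_points(s, chain, end - 1, "CA", "highest_occupancy")
    v <- as.numeric(ca2) - as.numeric(ca1)
  }
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate (zero-length) segment vector")
  v / n
}

#' Angle between two vectors, in degrees
#'
#' @param v1,v2 non-zero numeric 3-vectors.
#' @return angle in `[0, 180]` degrees.
#' @export
angle_between <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("angle undefined for zero vector")
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}
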