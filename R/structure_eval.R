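#' Load heavy-atom coordinates from a PDB file
#'
#' Reads a PDB file with bio3d, keeps the first model, drops hydrogens
#' (and deuterium), and resolves alternate locations by keeping the
#' highest-occupancy atom for each (chain, residue, atom name).
#'
#' @param structure A file path or a `bio3d` pdb object.
#' @return Data.frame of heavy atoms (bio3d atom-table columns).
#' @export
load_structure_atoms <- function(structure) {
  pdb <- if (is.character(structure)) {
    bio3d::read.pdb(structure, multi = FALSE, verbose = FALSE)
  } else structure
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  elt <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(trimws(at$elety), 1L, 1L), at$elesy)))
  at <- at[!(elt %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms found in structure")
  # altloc: keep the highest-occupancy copy of each atom
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at <- at[order(key, -occ), , drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")),
     , drop = FALSE]
}

chain_atoms <- function(atoms, chain) {
  sub <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0L) stop("chain not found in structure: ", chain)
  sub
}

#' Minimum heavy-atom distances between mapped residue pairs
#'
#' For every pair of mapped residues (one per chain) computes the minimum
#' Euclidean distance over all heavy-atom pairs. Residues in the map that
#' are missing from the structure are recorded as unresolved (NA
#' distance), not an error; a missing chain is fatal.
#'
#' @param structure File path or bio3d pdb object.
#' @param chain_a,chain_b Chain identifiers.
#' @param map_a,map_b Data.frames with columns `pos` (alignment/focus
#'   position) and `resno` (structure author residue number), one per
#'   chain.
#' @return An object of class `ev_distmap`: `dist` is a matrix indexed by
#'   the mapped positions of chain A (rows) and chain B (columns), NA for
#'   unresolved residues; `chain_a`, `chain_b` record the chains.
#' @export
min_atom_distances <- function(structure, chain_a, chain_b, map_a, map_b) {
  atoms <- load_structure_atoms(structure)
  aa <- chain_atoms(atoms, chain_a)
  ab <- chain_atoms(atoms, chain_b)
  stopifnot(all(c("pos", "resno") %in% names(map_a)),
            all(c("pos", "resno") %in% names(map_b)))
  coords_a <- split_residue_coords(aa, map_a$resno)
  coords_b <- split_residue_coords(ab, map_b$resno)
  d <- matrix(NA_real_, nrow(map_a), ncol = nrow(map_b),
              dimnames = list(as.character(map_a$pos),
                              as.character(map_b$pos)))
  for (i in seq_len(nrow(map_a))) {
    xa <- coords_a[[i]]
    if (is.null(xa)) next
    for (j in seq_len(nrow(map_b))) {
      xb <- coords_b[[j]]
      if (is.null(xb)) next
      d[i, j] <- min_pair_distance(xa, xb)
    }
  }
  base::structure(list(dist = d, chain_a = chain_a, chain_b = chain_b,
                       map_a = map_a, map_b = map_b),
                  class = "ev_distmap")
}

split_residue_coords <- function(atoms, resnos) {
  lapply(resnos, function(r) {
    sub <- atoms[atoms$resno == r, c("x", "y", "z"), drop = FALSE]
    if (nrow(sub) == 0L) NULL else as.matrix(sub)
  })
}

min_pair_distance <- function(xa, xb) {
  # all-pairs squared distances via the expanded inner product
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

#' Look up a residue-pair distance
#'
#' @param dmap An `ev_distmap`.
#' @param pos_a,pos_b Positions as used in the distance map (either
#'   orientation is accepted).
#' @return Numeric distance, or NA when the pair is unresolved or absent.
#' @export
dmap_lookup <- function(dmap, pos_a, pos_b) {
  ra <- as.character(pos_a); cb <- as.character(pos_b)
  get1 <- function(r, cc) {
    if (r %in% rownames(dmap$dist) && cc %in% colnames(dmap$dist)) {
      dmap$dist[r, cc]
    } else NA_real_
  }
  d <- mapply(get1, ra, cb)
  swapped <- mapply(get1, cb, ra)
  ifelse(is.na(d), swapped, d)
}

#' Precision of predicted contacts against a structure
#'
#' A predicted pair is a true positive when its minimum heavy-atom
#' distance is at most `cutoff` (8 Angstrom by default), a false positive
#' when it is resolved but further away; pairs unresolved in the
#' structure are excluded from the ratio, and
#' `precision = TP / (TP + FP)`.
#'
#' @param contacts Data.frame with `pos_a`, `pos_b` columns.
#' @param dmap An `ev_distmap`.
#' @param cutoff Distance cutoff in Angstrom (default 8; 5/10/12 are the
#'   other conventional cutoffs).
#' @return An object of class `ev_precision`: `cutoff_angstrom`, `tp`,
#'   `fp`, `unresolved`, `precision` (NA when no pair is resolved,
#'   flagged via `defined = FALSE`).
#' @export
contact_precision <- function(contacts, dmap, cutoff = 8.0) {
  if (nrow(contacts) == 0L) stop("no contacts to evaluate")
  d <- dmap_lookup(dmap, contacts$pos_a, contacts$pos_b)
  unresolved <- sum(is.na(d))
  tp <- sum(d <= cutoff, na.rm = TRUE)
  fp <- sum(d > cutoff, na.rm = TRUE)
  structure(list(cutoff_angstrom = cutoff, tp = tp, fp = fp,
                 unresolved = unresolved,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 defined = tp + fp > 0),
            class = "ev_precision")
}

#' @export
print.ev_precision <- function(x, ...) {
  cat(sprintf(
    "precision at %.1f A: %s (TP = %d, FP = %d, unresolved = %d)\n",
    x$cutoff_angstrom,
    if (x$defined) sprintf("%.3f", x$precision) else "undefined",
    x$tp, x$fp, x$unresolved))
  invisible(x)
}

#' Long-format contact-map table
#'
#' Combines intra- and inter-protein predictions with structure distances
#' into the long-format table behind quadrant contact-map plots. Each
#' row carries its block label, score, distance where known, and a
#' distance class binned at the 5/8/12 Angstrom cutoffs.
#'
#' @param contacts Data.frame with `pos_a`, `pos_b`, `block` (one of
#'   `intra_a`, `intra_b`, `inter`) and `score` columns.
#' @param dmaps A single `ev_distmap` applied to every row, or a named
#'   list of maps keyed by block label.
#' @return Data.frame with appended `distance` and `distance_class`
#'   (`"<=5"`, `"<=8"`, `"<=12"`, `">12"`, `"unresolved"`).
#' @export
contact_map_table <- function(contacts, dmaps) {
  stopifnot(all(c("pos_a", "pos_b", "block", "score") %in% names(contacts)))
  lookup_block <- function(block, pa, pb) {
    dm <- if (inherits(dmaps, "ev_distmap")) dmaps else dmaps[[block]]
    if (is.null(dm)) return(NA_real_)
    dmap_lookup(dm, pa, pb)
  }
  d <- vapply(seq_len(nrow(contacts)), function(k) {
    lookup_block(contacts$block[k], contacts$pos_a[k], contacts$pos_b[k])
  }, numeric(1))
  cls <- ifelse(is.na(d), "unresolved",
                ifelse(d <= 5, "<=5",
                       ifelse(d <= 8, "<=8",
                              ifelse(d <= 12, "<=12", ">12"))))
  contacts$distance <- d
  contacts$distance_class <- cls
  contacts
}

#' Interface residues of a two-chain complex
#'
#' Residues of each chain containing any heavy atom strictly closer than
#' `cutoff` (6 Angstrom by default) to any heavy atom of the partner
#' chain.
#'
#' @param structure File path or bio3d pdb object.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Strict distance cutoff in Angstrom (default 6).
#' @return List with sorted residue-number vectors `chain_a`, `chain_b`.
#' @export
interface_residues <- function(structure, chain_a, chain_b, cutoff = 6.0) {
  atoms <- load_structure_atoms(structure)
  aa <- chain_atoms(atoms, chain_a)
  ab <- chain_atoms(atoms, chain_b)
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  close <- d2 < cutoff^2
  list(chain_a = sort(unique(aa$resno[rowSums(close) > 0])),
       chain_b = sort(unique(ab$resno[colSums(close) > 0])))
}

#' Write CNS/HADDOCK unambiguous distance restraints
#'
#' One `assign` statement per predicted contact, restraining the
#' Calpha-Calpha distance to `d_eff` with the given lower/upper bounds
#' (defaults 5.0, 2.0, 2.0 Angstrom), segid-qualified by chain.
#'
#' @param contacts Data.frame with structure residue numbers `res_a`,
#'   `res_b`.
#' @param chain_a,chain_b Segids for the two chains.
#' @param path Output `.tbl` path.
#' @param d_eff Target distance (default 5.0).
#' @param lower,upper Bounds below/above `d_eff` (default 2.0 each).
#' @return Invisibly, `path`.
#' @export
write_haddock_restraints <- function(contacts, chain_a, chain_b, path,
                                     d_eff = 5.0, lower = 2.0,
                                     upper = 2.0) {
  if (nrow(contacts) == 0L) {
    stop("no contacts: refusing to write an empty restraint file")
  }
  stopifnot(all(c("res_a", "res_b") %in% names(contacts)))
  lines <- sprintf(
    "assign (segid %s and resid %d and name CA) (segid %s and resid %d and name CA) %.1f %.1f %.1f",
    chain_a, as.integer(contacts$res_a),
    chain_b, as.integer(contacts$res_b),
    d_eff, lower, upper)
  writeLines(lines, path)
  invisible(path)
}

#' Parse a CNS/HADDOCK restraint table
#'
#' Round-trip reader for files produced by
#' [write_haddock_restraints()].
#'
#' @param path Restraint `.tbl` path.
#' @return Data.frame with `segid_a`, `res_a`, `segid_b`, `res_b`,
#'   `d_eff`, `lower`, `upper`.
#' @export
read_haddock_restraints <- function(path) {
  lines <- grep("^assign", readLines(path), value = TRUE)
  pat <- paste0("^assign \\(segid ([^ ]+) and resid ([0-9]+) and name CA\\)",
                " \\(segid ([^ ]+) and resid ([0-9]+) and name CA\\)",
                " ([0-9.]+) ([0-9.]+) ([0-9.]+)$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- lengths(m) != 8L
  if (any(bad)) stop("unparsable restraint line: ", lines[which(bad)[1L]])
  m <- do.call(rbind, m)
  data.frame(segid_a = m[, 2L], res_a = as.integer(m[, 3L]),
             segid_b = m[, 4L], res_b = as.integer(m[, 5L]),
             d_eff = as.numeric(m[, 6L]), lower = as.numeric(m[, 7L]),
             upper = as.numeric(m[, 8L]))
}
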