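# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately recompute quantities with naive double loops or
# direct formulas, sharing no code path with the package implementation.

aa_symbols <- aa_alphabet()$symbols

random_alignment_matrix <- function(n, L, symbols = aa_symbols) {
  matrix(sample(symbols, n * L, replace = TRUE), n, L)
}

# O(N^2 L) pairwise-identity weights (gaps count as symbols, full-length
# denominator).
bf_sequence_weights <- function(mat, threshold = 0.8) {
  n <- nrow(mat); L <- ncol(mat)
  counts <- integer(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (sum(mat[s, ] == mat[t, ]) / L >= threshold) {
        counts[s] <- counts[s] + 1L
      }
    }
  }
  1 / counts
}

# Direct mean-formula average product correction.
bf_apc <- function(m, exclude_diagonal = TRUE) {
  n <- nrow(m)
  rowm <- numeric(n)
  for (i in seq_len(n)) {
    idx <- if (exclude_diagonal) setdiff(seq_len(n), i) else seq_len(n)
    rowm[i] <- mean(m[i, idx])
  }
  if (exclude_diagonal) {
    tot <- mean(m[row(m) != col(m)])
  } else {
    tot <- mean(m)
  }
  out <- m
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- m[i, j] - rowm[i] * rowm[j] / tot
  }
  out
}

# Interval gap recomputed from endpoint case analysis.
bf_interval_gap <- function(s1, e1, s2, e2) {
  if (s1 > e2) s1 - e2 else if (s2 > e1) s2 - e1 else 0L
}

# Exhaustive greedy pairing: at every step all admissible pairs of the
# species are re-enumerated from the raw tables and the minimum under the
# tie rule (distance, contig, A start, B start, A accession, B accession)
# is taken; both loci are then removed.
bf_match_pairs <- function(loci_a, loci_b, max_nt = 10000) {
  res <- list()
  for (sp in sort(intersect(unique(loci_a$species), unique(loci_b$species)))) {
    la <- loci_a[loci_a$species == sp, , drop = FALSE]
    lb <- loci_b[loci_b$species == sp, , drop = FALSE]
    repeat {
      best <- NULL
      for (i in seq_len(nrow(la))) {
        for (j in seq_len(nrow(lb))) {
          if (la$contig_id[i] != lb$contig_id[j]) next
          d <- bf_interval_gap(la$nt_start[i], la$nt_end[i],
                               lb$nt_start[j], lb$nt_end[j])
          if (d > max_nt) next
          key <- list(d, la$contig_id[i], la$nt_start[i], lb$nt_start[j],
                      la$accession[i], lb$accession[j])
          if (is.null(best) || tuple_less(key, best$key)) {
            best <- list(i = i, j = j, d = d, key = key)
          }
        }
      }
      if (is.null(best)) break
      res[[length(res) + 1L]] <- data.frame(
        species_key = sp,
        accession_a = la$accession[best$i],
        accession_b = lb$accession[best$j],
        contig_id = la$contig_id[best$i],
        nt_distance = as.integer(best$d),
        stringsAsFactors = FALSE)
      la <- la[-best$i, , drop = FALSE]
      lb <- lb[-best$j, , drop = FALSE]
    }
  }
  if (length(res) == 0L) {
    return(data.frame(species_key = character(0),
                      accession_a = character(0),
                      accession_b = character(0),
                      contig_id = character(0),
                      nt_distance = integer(0)))
  }
  do.call(rbind, res)
}

tuple_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[[k]] < b[[k]]) return(TRUE)
    if (a[[k]] > b[[k]]) return(FALSE)
  }
  FALSE
}

# --- toy PDB construction ---------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, elesy = substr(name, 1L, 1L),
                          alt = "") {
  sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, formatC(name, width = 4, flag = "-"), alt, resname, chain,
    resno, x, y, z, occ, 0, elesy)
}

# atoms: data.frame(name, resname, chain, resno, x, y, z [, occ, elesy,
# alt])
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(atoms)), function(k) {
    a <- atoms[k, ]
    pdb_atom_line(k, a$name, a$resname %||na% "ALA", a$chain, a$resno,
                  a$x, a$y, a$z,
                  occ = a$occ %||na% 1,
                  elesy = a$elesy %||na% substr(a$name, 1L, 1L),
                  alt = a$alt %||na% "")
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||na%` <- function(x, y) if (is.null(x) || all(is.na(x))) y else x

# Brute-force minimum heavy-atom distance between two residues given
# coordinate data.frames with x, y, z.
bf_min_distance <- function(atoms_a, atoms_b) {
  best <- Inf
  for (i in seq_len(nrow(atoms_a))) {
    for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                  (atoms_a$y[i] - atoms_b$y[j])^2 +
                  (atoms_a$z[i] - atoms_b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# --- planted-recovery helper ------------------------------------------

# Fraction of the top-k inter-block APC scores that are planted pairs.
recovery_precision <- function(truth, n, sample_seed,
                               k = nrow(truth$inter_pairs)) {
  aln <- sample_potts(truth$model, n, seed = sample_seed)
  w <- sequence_weights(aln)
  enc <- encode_alignment(aln, aa_alphabet(truth$q))
  model <- fit_plm(enc, w, q = truth$q)
  cpl <- apply_apc(coupling_scores(model, boundary = truth$boundary))
  inter <- inter_couplings(cpl)
  top <- inter[order(-inter$raw_ec), ][seq_len(k), ]
  planted <- paste(truth$inter_pairs$i, truth$inter_pairs$j)
  sum(paste(top$i, top$j) %in% planted) / k
}
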