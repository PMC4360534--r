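#' Read a gene-location table
#'
#' Tab-separated table with columns `accession`, `species`, `contig_id`,
#' `nt_start`, `nt_end`, `gene_index`, one row per homolog CDS. The
#' accession must match the alignment identifier (residue-range suffixes
#' are ignored when rows are looked up).
#'
#' @param path File path.
#' @return A data.frame of gene loci.
#' @export
read_gene_loci <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_loci(df)
}

validate_gene_loci <- function(df) {
  need <- c("accession", "species", "contig_id", "nt_start", "nt_end",
            "gene_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene-location table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(is.na(df$gene_index))) stop("missing gene_index in locus table")
  if (any(df$nt_end <= df$nt_start)) stop("nt_end must exceed nt_start")
  if (any(df$nt_start < 0)) stop("nt_start must be >= 0")
  df
}

#' Write a gene-location table
#' @param loci Data.frame as returned by [read_gene_loci()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_loci <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene distance between two loci
#'
#' Number of genes lying between two CDS on the same contig:
#' `|gene_index_a - gene_index_b| - 1`, floored at 0 for adjacent genes.
#' Returns `NA` when the loci sit on different contigs (distance
#' undefined).
#'
#' @param a,b Single-row data.frames (or named lists) with `contig_id` and
#'   `gene_index`.
#' @return Integer gene distance, or `NA_integer_` across contigs.
#' @export
gene_distance <- function(a, b) {
  if (is.null(a$gene_index) || is.null(b$gene_index) ||
      is.na(a$gene_index) || is.na(b$gene_index)) {
    stop("gene_index missing: cannot compute gene distance")
  }
  if (a$contig_id != b$contig_id) return(NA_integer_)
  max(0L, abs(as.integer(a$gene_index) - as.integer(b$gene_index)) - 1L)
}

#' Nucleotide distance between two CDS intervals
#'
#' Gap in nucleotides between the two intervals on the same contig; 0 if
#' they abut or overlap.
#'
#' @param a,b Single-row data.frames (or named lists) with `contig_id`,
#'   `nt_start`, `nt_end`.
#' @return Non-negative integer distance.
#' @export
nt_distance <- function(a, b) {
  if (a$contig_id != b$contig_id) {
    stop("nt distance undefined across contigs")
  }
  max(0L, as.integer(max(a$nt_start, b$nt_start)) -
        as.integer(min(a$nt_end, b$nt_end)))
}

#' Match interacting homolog pairs by genomic proximity
#'
#' Within each species, candidate pairings are restricted to loci on the
#' same contig no further apart than `max_nt` nucleotides (pairs at a
#' distance strictly greater than `max_nt` are excluded). Pairs are then
#' chosen by iterative greedy matching: the globally closest admissible
#' pair in the species is taken, both loci are removed, and the scan
#' repeats, so each locus is used at most once. Ties in distance are
#' broken by (contig_id, nt_start of A, nt_start of B, accession of A,
#' accession of B), making the matching deterministic and seed-free.
#' Several paralog pairs per species are allowed when each satisfies the
#' rules.
#'
#' @param loci_a,loci_b Gene-location data.frames (see
#'   [read_gene_loci()]) for the homologs of proteins A and B.
#' @param max_nt Maximum nucleotide distance between paired CDS
#'   (default 10000).
#' @return A data.frame of matched pairs: `species_key`, `accession_a`,
#'   `accession_b`, `contig_id`, `nt_distance`.
#' @export
match_pairs <- function(loci_a, loci_b, max_nt = 10000L) {
  stopifnot(max_nt > 0)
  loci_a <- validate_gene_loci(loci_a)
  loci_b <- validate_gene_loci(loci_b)
  shared <- intersect(unique(loci_a$species), unique(loci_b$species))
  if (length(shared) == 0L) {
    warning("no species shared between the two locus tables")
  }
  out <- list()
  for (sp in sort(shared)) {
    la <- loci_a[loci_a$species == sp, , drop = FALSE]
    lb <- loci_b[loci_b$species == sp, , drop = FALSE]
    if (nrow(la) == 0L || nrow(lb) == 0L) next
    grid <- expand.grid(ia = seq_len(nrow(la)), ib = seq_len(nrow(lb)))
    same <- la$contig_id[grid$ia] == lb$contig_id[grid$ib]
    grid <- grid[same, , drop = FALSE]
    if (nrow(grid) == 0L) next
    d <- mapply(function(ia, ib) nt_distance(la[ia, ], lb[ib, ]),
                grid$ia, grid$ib)
    keep <- d <= max_nt
    grid <- grid[keep, , drop = FALSE]
    d <- d[keep]
    if (nrow(grid) == 0L) next
    ord <- order(d, la$contig_id[grid$ia], la$nt_start[grid$ia],
                 lb$nt_start[grid$ib], la$accession[grid$ia],
                 lb$accession[grid$ib])
    grid <- grid[ord, , drop = FALSE]
    d <- d[ord]
    used_a <- logical(nrow(la)); used_b <- logical(nrow(lb))
    for (k in seq_len(nrow(grid))) {
      ia <- grid$ia[k]; ib <- grid$ib[k]
      if (used_a[ia] || used_b[ib]) next
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        species_key = sp,
        accession_a = la$accession[ia],
        accession_b = lb$accession[ib],
        contig_id = la$contig_id[ia],
        nt_distance = as.integer(d[k]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(species_key = character(0),
                      accession_a = character(0),
                      accession_b = character(0),
                      contig_id = character(0),
                      nt_distance = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Concatenate two alignments along matched pairs
#'
#' Row k of the result joins the A-alignment row for `accession_a[k]` with
#' the B-alignment row for `accession_b[k]`. The A/B boundary is recorded
#' (`boundary = L_A`) together with both per-protein column maps so that
#' downstream scores can be reported in each protein's focus numbering.
#'
#' @param aln_a,aln_b `ev_alignment` objects.
#' @param pairs Data.frame from [match_pairs()].
#' @return An object of class `ev_concat` with fields `matrix`, `ids`,
#'   `species`, `boundary`, `pairs`, `column_maps` (list `a`, `b`).
#' @export
concatenate_alignments <- function(aln_a, aln_b, pairs) {
  if (nrow(pairs) == 0L) stop("no matched pairs: empty concatenated alignment")
  acc_a <- accession_of(aln_a$ids)
  acc_b <- accession_of(aln_b$ids)
  row_a <- match(pairs$accession_a, acc_a)
  row_b <- match(pairs$accession_b, acc_b)
  if (any(is.na(row_a)) || any(is.na(row_b))) {
    stop("pair accession not found in alignment ids")
  }
  if (anyDuplicated(row_a) || anyDuplicated(row_b)) {
    stop("duplicate row usage in pairing")
  }
  mat <- cbind(aln_a$matrix[row_a, , drop = FALSE],
               aln_b$matrix[row_b, , drop = FALSE])
  structure(
    list(matrix = mat,
         ids = paste(pairs$accession_a, pairs$accession_b, sep = "&"),
         species = pairs$species_key,
         boundary = ncol(aln_a$matrix),
         pairs = cbind(pairs, row_a = row_a, row_b = row_b),
         column_maps = list(a = aln_a$column_map, b = aln_b$column_map)),
    class = "ev_concat")
}

#' @export
print.ev_concat <- function(x, ...) {
  cat(sprintf(
    "ev_concat: %d paired sequences x %d columns (boundary at %d)\n",
    nrow(x$matrix), ncol(x$matrix), x$boundary))
  invisible(x)
}
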