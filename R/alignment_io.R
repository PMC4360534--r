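#' Multiple sequence alignment container
#'
#' Holds a rectangular alignment with per-sequence identifiers and species
#' tags, the index of the focus (query) sequence, and a column map giving,
#' for each alignment column, the residue number of the focus sequence at
#' that column (NA where the focus sequence has a gap). Residue numbering
#' starts at the focus range start parsed from an `id/start-end` suffix,
#' or 1 when no range is present.
#'
#' @param matrix Character matrix (N x L) of aligned symbols.
#' @param ids Character vector of N sequence identifiers.
#' @param species Character vector of N species tags (NA allowed), or NULL
#'   to parse them from `ids` with [parse_species_tags()].
#' @param focus Index of the focus sequence (default 1, the first record,
#'   following the jackhmmer convention that the query comes first).
#' @param species_pattern Regular expression with one capture group used
#'   to extract the species tag from an identifier.
#' @return An object of class `ev_alignment`.
#' @export
new_alignment <- function(matrix, ids, species = NULL, focus = 1L,
                          species_pattern = default_species_pattern()) {
  if (!is.matrix(matrix) || !is.character(matrix)) {
    stop("alignment matrix must be a character matrix")
  }
  if (nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop("empty alignment: need at least one sequence and one column")
  }
  if (length(ids) != nrow(matrix)) stop("ids length must equal row count")
  matrix <- canonicalize_symbols(matrix)
  if (is.null(species)) species <- parse_species_tags(ids, species_pattern)
  focus <- as.integer(focus)
  if (focus < 1L || focus > nrow(matrix)) stop("focus index out of range")
  aln <- structure(
    list(matrix = matrix, ids = as.character(ids),
         species = as.character(species), focus = focus,
         column_map = focus_column_map(matrix[focus, ], ids[focus])),
    class = "ev_alignment")
  validate_alignment(aln)
  aln
}

#' @export
print.ev_alignment <- function(x, ...) {
  cat(sprintf("ev_alignment: %d sequences x %d columns (focus: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$ids[x$focus]))
  invisible(x)
}

validate_alignment <- function(aln) {
  stopifnot(is.matrix(aln$matrix), nrow(aln$matrix) >= 1L)
  if (length(aln$ids) != nrow(aln$matrix)) stop("ids/matrix mismatch")
  if (aln$focus < 1L || aln$focus > nrow(aln$matrix)) stop("bad focus index")
  cm <- aln$column_map[!is.na(aln$column_map)]
  if (length(cm) > 1L && any(diff(cm) <= 0L)) {
    stop("column_map must be strictly increasing")
  }
  ok <- aln$matrix %in% aa_alphabet(21L)$symbols
  if (!all(ok)) stop("non-canonical symbols present after canonicalization")
  invisible(aln)
}

#' Default species-tag pattern
#'
#' The species key is taken from the identifier suffix after the last
#' underscore, after stripping a trailing `/start-end` range — the UniProt
#' entry-name convention (`GENE_SPECIES`). The rule is configurable
#' because header grammars vary between alignment pipelines.
#' @return A regular expression with one capture group.
#' @export
default_species_pattern <- function() "_([^_/[:space:]]+)$"

#' Parse species tags from sequence identifiers
#'
#' @param ids Character vector of identifiers.
#' @param pattern Regular expression with one capture group; applied after
#'   stripping a trailing `/start-end` residue range.
#' @return Character vector of species tags; NA where the pattern fails.
#' @export
parse_species_tags <- function(ids, pattern = default_species_pattern()) {
  base <- sub("/-?[0-9]+--?[0-9]+$", "", ids)
  m <- regmatches(base, regexec(pattern, base))
  vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_,
         character(1))
}

# Accession = identifier without the residue-range suffix.
accession_of <- function(ids) sub("/-?[0-9]+--?[0-9]+$", "", ids)

focus_range_start <- function(id) {
  m <- regmatches(id, regexec("/([0-9]+)-([0-9]+)$", id))[[1L]]
  if (length(m) == 3L) as.integer(m[2L]) else 1L
}

focus_column_map <- function(focus_row, focus_id) {
  start <- focus_range_start(focus_id)
  cm <- rep(NA_integer_, length(focus_row))
  nongap <- focus_row != "-"
  cm[nongap] <- start - 1L + seq_len(sum(nongap))
  cm
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (via Biostrings) or Stockholm format, canonicalizes symbols
#' (uppercase; non-standard residue codes and "." mapped to gap) and
#' returns an [new_alignment()] object. The focus sequence defaults to the
#' first record.
#'
#' @param path File path.
#' @param format `"fasta"` or `"stockholm"`.
#' @param focus Focus-sequence row index.
#' @param species_pattern See [parse_species_tags()].
#' @return An `ev_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           focus = 1L,
                           species_pattern = default_species_pattern()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) stop("empty alignment file: ", path)
    if (length(unique(Biostrings::width(recs))) != 1L) {
      stop("ragged FASTA records: all aligned rows must have equal length")
    }
    if (Biostrings::width(recs)[1L] == 0L) stop("zero-length records")
    ids <- sub("[[:space:]].*$", "", names(recs))
    mat <- do.call(rbind, strsplit(as.character(recs), "", fixed = TRUE))
  } else {
    parsed <- read_stockholm_lines(readLines(path))
    ids <- parsed$ids
    mat <- parsed$matrix
  }
  new_alignment(mat, ids, focus = focus,
                species_pattern = species_pattern)
}

read_stockholm_lines <- function(lines) {
  if (length(lines) == 0L) stop("empty alignment file")
  seqs <- list()
  order_seen <- character(0)
  for (ln in lines) {
    if (grepl("^#", ln) || grepl("^//", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(parts) != 2L) stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1L]
    if (!id %in% order_seen) order_seen <- c(order_seen, id)
    seqs[[id]] <- paste0(seqs[[id]] %||% "", parts[2L])
  }
  if (length(seqs) == 0L) stop("no sequences found in Stockholm input")
  chars <- strsplit(unlist(seqs[order_seen], use.names = FALSE), "",
                    fixed = TRUE)
  if (length(unique(lengths(chars))) != 1L) {
    stop("ragged Stockholm records: unequal aligned lengths")
  }
  list(ids = order_seen, matrix = do.call(rbind, chars))
}

#' Write a multiple sequence alignment
#'
#' Writes FASTA (gap as `-`) or single-block Stockholm. A written
#' alignment read back with [read_alignment()] reproduces the matrix and
#' identifiers exactly.
#'
#' @param aln An `ev_alignment` (or `ev_concat`).
#' @param path Output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (nrow(aln$matrix) < 1L) stop("refusing to write an empty alignment")
  rows <- apply(aln$matrix, 1L, paste0, collapse = "")
  if (format == "fasta") {
    xs <- Biostrings::BStringSet(rows)
    names(xs) <- aln$ids
    Biostrings::writeXStringSet(xs, filepath = path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# STOCKHOLM 1.0", con)
    width <- max(nchar(aln$ids)) + 2L
    writeLines(sprintf(paste0("%-", width, "s%s"), aln$ids, rows), con)
    writeLines("//", con)
  }
  invisible(path)
}
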