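#' Remove gap-dominated alignment columns
#'
#' Columns whose gap fraction is strictly greater than `max_gap_fraction`
#' are excluded (a column with exactly the threshold fraction is kept).
#' Column maps and, for concatenated alignments, the A/B boundary are
#' updated consistently, and the removed-column indices are retained in
#' the `removed_columns` attribute. The operation is idempotent.
#'
#' @param x An `ev_alignment` or `ev_concat`.
#' @param max_gap_fraction Maximum tolerated gap fraction (default 0.8).
#' @return Object of the same class with offending columns removed.
#' @export
filter_gap_columns <- function(x, max_gap_fraction = 0.8) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1)
  gap_frac <- colMeans(x$matrix == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("all columns removed by gap filtering")
  removed <- which(!keep)
  x$matrix <- x$matrix[, keep, drop = FALSE]
  if (inherits(x, "ev_concat")) {
    keep_a <- keep[seq_len(x$boundary)]
    keep_b <- keep[-seq_len(x$boundary)]
    if (!any(keep_a) || !any(keep_b)) {
      stop("gap filtering removed one protein entirely")
    }
    x$column_maps$a <- x$column_maps$a[keep_a]
    x$column_maps$b <- x$column_maps$b[keep_b]
    x$boundary <- sum(keep_a)
  } else {
    x$column_map <- x$column_map[keep]
  }
  attr(x, "removed_columns") <- removed
  x
}

#' Identity-based sequence weights and effective sequence number
#'
#' Each sequence is down-weighted by the size of its identity cluster:
#' `weight_s = 1 / |{t : identity(s, t) >= threshold}|`, counting the
#' sequence itself, where identity is the fraction of matching symbols
#' over the full alignment length (gap positions count as symbols). With
#' the default 80% threshold, sequences with 80% or more identical
#' residues are clustered together, implicitly removing duplicates. The
#' effective number of sequences is `n_eff = sum(weights)`.
#'
#' @param x An `ev_alignment`, `ev_concat`, or character matrix.
#' @param identity_threshold Clustering threshold in (0, 1]; comparison is
#'   inclusive (`>=`). Default 0.8; monomer-style runs conventionally use
#'   0.9.
#' @return An object of class `ev_seqweights` with `weights`, `n_eff` and
#'   `identity_threshold`.
#' @export
sequence_weights <- function(x, identity_threshold = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  m <- if (is.matrix(x)) x else x$matrix
  if (nrow(m) < 1L) stop("empty alignment")
  enc <- encode_alignment(m)
  n <- nrow(enc); L <- ncol(enc); q <- max(enc)
  # pairwise identity counts via one-hot cross-product (exact, O(N^2 L))
  Z <- matrix(0, n, L * q)
  Z[cbind(rep(seq_len(n), L),
          as.vector(t(t(enc) + (seq_len(L) - 1L) * q)))] <- 1
  matches <- tcrossprod(Z)
  neighbours <- rowSums(matches / L >= identity_threshold - 1e-12)
  w <- 1 / neighbours
  structure(list(weights = w, n_eff = sum(w),
                 identity_threshold = identity_threshold),
            class = "ev_seqweights")
}

#' @export
print.ev_seqweights <- function(x, ...) {
  cat(sprintf("ev_seqweights: N = %d, N_eff = %.2f (identity >= %g)\n",
              length(x$weights), x$n_eff, x$identity_threshold))
  invisible(x)
}

#' Preprocessing report for a concatenated alignment
#'
#' Applies gap-column filtering then sequence reweighting and summarizes
#' the quantities that determine downstream score normalization: N,
#' N_eff, post-filter length L and N_eff/L.
#'
#' @param concat An `ev_concat`.
#' @param max_gap_fraction See [filter_gap_columns()].
#' @param identity_threshold See [sequence_weights()].
#' @return A list with `concat` (filtered), `weights`, and `report`
#'   (n_sequences, n_columns_removed, length_total, n_eff, neff_per_l).
#' @export
preprocess_concat <- function(concat, max_gap_fraction = 0.8,
                              identity_threshold = 0.8) {
  filtered <- filter_gap_columns(concat, max_gap_fraction)
  w <- sequence_weights(filtered, identity_threshold)
  L <- ncol(filtered$matrix)
  list(concat = filtered, weights = w,
       report = list(
         n_sequences = nrow(filtered$matrix),
         n_columns_removed = length(attr(filtered, "removed_columns")),
         length_total = L,
         boundary = filtered$boundary,
         n_eff = w$n_eff,
         neff_per_l = w$n_eff / L))
}
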