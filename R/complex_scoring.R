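#' Scoring configuration
#'
#' Thresholds for contact calling and subunit-interaction classification:
#' inter-protein contacts are selected at EVcomplex score >= 0.8, subunit
#' pairs are called interacting above 0.8, weakly predicted between 0.75
#' and 0.8, and rejected below 0.75; alignments with
#' `N_eff / L <= 0.3` fail the sequence-sufficiency filter.
#'
#' @param contact_threshold Contact-calling threshold (default 0.8).
#' @param weak_lower Lower bound of the weak band (default 0.75).
#' @param sufficiency_min Minimum `N_eff / L` ratio, strict (default 0.3).
#' @return An object of class `ev_scoring_config`.
#' @export
scoring_config <- function(contact_threshold = 0.8, weak_lower = 0.75,
                           sufficiency_min = 0.3) {
  stopifnot(weak_lower > 0, weak_lower <= contact_threshold,
            sufficiency_min > 0)
  structure(list(contact_threshold = contact_threshold,
                 weak_lower = weak_lower,
                 sufficiency_min = sufficiency_min),
            class = "ev_scoring_config")
}

#' Extract the inter-protein coupling block
#'
#' All residue pairs crossing the concatenation boundary, with positions
#' reported both as alignment columns (i, j) and in each protein's focus
#' numbering (pos_a, pos_b) when column maps are supplied.
#'
#' @param couplings An `ev_couplings` with a non-NULL boundary
#'   (conventionally after [apply_apc()]).
#' @param column_maps Optional list(a =, b =) of per-protein column maps.
#' @return Data.frame with columns i, j, pos_a, pos_b, raw_ec.
#' @export
inter_couplings <- function(couplings, column_maps = NULL) {
  b <- couplings$boundary
  if (is.null(b)) stop("couplings carry no boundary: not a complex run")
  L <- couplings$L
  grid <- expand.grid(i = seq_len(b), j = seq(b + 1L, L))
  pos_a <- if (is.null(column_maps)) grid$i else column_maps$a[grid$i]
  pos_b <- if (is.null(column_maps)) grid$j - b else column_maps$b[grid$j - b]
  data.frame(i = grid$i, j = grid$j, pos_a = pos_a, pos_b = pos_b,
             raw_ec = couplings$scores[cbind(grid$i, grid$j)])
}

#' Raw reliability ratio of inter-protein couplings
#'
#' The background of non-coupled pair scores is approximately symmetric
#' around zero, so its width can be estimated by the absolute value of
#' the minimum inter-protein score. The raw reliability (pair coupling
#' score ratio) of each pair is its score divided by that width:
#' `q_raw(i, j) = raw_ec(i, j) / |min raw_ec|`. The ratio is invariant
#' under positive rescaling of all scores, and the minimum-scoring pair
#' always has `q_raw = -1`.
#'
#' @param inter Data.frame with a `raw_ec` column (see
#'   [inter_couplings()]).
#' @return The same data.frame with a `q_raw` column appended.
#' @export
raw_reliability <- function(inter) {
  if (!is.data.frame(inter) || !"raw_ec" %in% names(inter)) {
    stop("expected a data.frame with a raw_ec column")
  }
  if (nrow(inter) == 0L) stop("empty inter-protein coupling block")
  m <- min(inter$raw_ec)
  if (m >= 0) {
    stop(paste0(
      "background width undefined: no negative inter-protein score, so ",
      "the symmetric-background assumption cannot be applied. Check that ",
      "the average product correction was applied to the coupling matrix ",
      "before extracting the inter block."))
  }
  inter$q_raw <- inter$raw_ec / abs(m)
  inter
}

#' Normalized EVcomplex scores
#'
#' Normalizes the raw reliability ratio by alignment depth so one
#' threshold is comparable across protein pairs:
#' `score = q_raw / (1 + (n_eff / L)^(-1/2))`, where `n_eff` is the
#' effective number of sequences after redundancy reduction and `L` is
#' the length of the concatenated alignment. Predictions are returned
#' ranked by descending score.
#'
#' @param scored Data.frame with a `q_raw` column (see
#'   [raw_reliability()]).
#' @param n_eff Effective sequence number (> 0).
#' @param L Concatenated alignment length (> 0).
#' @return The data.frame with `evcomplex_score` and `rank` columns,
#'   sorted by rank.
#' @export
evcomplex_scores <- function(scored, n_eff, L) {
  stopifnot(n_eff > 0, L > 0)
  if (!"q_raw" %in% names(scored)) stop("expected a q_raw column")
  denom <- 1 + (n_eff / L)^(-1 / 2)
  scored$evcomplex_score <- scored$q_raw / denom
  ord <- order(-scored$evcomplex_score, scored$pos_a %||% scored$q_raw,
               scored$pos_b %||% scored$q_raw)
  scored <- scored[ord, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored
}

#' Sequence-sufficiency check
#'
#' Coupling inference is only statistically meaningful with enough
#' non-redundant sequences per residue; the filter requires
#' `n_eff / L` strictly greater than `min_ratio` (default 0.3).
#'
#' @param n_eff Effective sequence number.
#' @param L Alignment length.
#' @param min_ratio Strict lower bound on the ratio (default 0.3).
#' @return TRUE iff `n_eff / L > min_ratio`.
#' @export
sufficiency_check <- function(n_eff, L, min_ratio = 0.3) {
  stopifnot(n_eff > 0, L > 0, min_ratio > 0)
  (n_eff / L) > min_ratio
}

#' Select predicted inter-protein contacts
#'
#' All predictions with EVcomplex score at or above the contact threshold
#' (>= 0.8 by default; the boundary value is included), rank-ordered with
#' ties broken by (pos_a, pos_b). An empty selection is allowed.
#'
#' @param predictions Data.frame with `evcomplex_score` (see
#'   [evcomplex_scores()]).
#' @param config An [scoring_config()].
#' @return The selected rows, re-ranked.
#' @export
select_contacts <- function(predictions, config = scoring_config()) {
  if (nrow(predictions) == 0L) return(predictions)
  sel <- predictions[predictions$evcomplex_score >= config$contact_threshold,
                     , drop = FALSE]
  if (nrow(sel) == 0L) return(sel)
  sel <- sel[order(-sel$evcomplex_score, sel$pos_a, sel$pos_b), ,
             drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Classify a subunit pair as interacting
#'
#' The highest EVcomplex score over the pair's inter-protein block serves
#' as a proxy for the likelihood of interaction: `interacting` at or
#' above the contact threshold, `weak` from `weak_lower` up to the
#' threshold, `rejected` below. The boundary values classify as 0.8 ->
#' interacting (consistent with the >= 0.8 contact rule) and 0.75 ->
#' weak.
#'
#' @param best_score Maximum EVcomplex score of the pair.
#' @param config An [scoring_config()].
#' @param pair_id Optional label for the subunit pair.
#' @return An object of class `ev_interaction_call` with `pair_id`,
#'   `best_score`, `label`.
#' @export
classify_interaction <- function(best_score, config = scoring_config(),
                                 pair_id = NA_character_) {
  stopifnot(is.numeric(best_score), length(best_score) == 1L)
  label <- if (best_score >= config$contact_threshold) {
    "interacting"
  } else if (best_score >= config$weak_lower) {
    "weak"
  } else {
    "rejected"
  }
  structure(list(pair_id = pair_id, best_score = best_score, label = label),
            class = "ev_interaction_call")
}

#' @export
print.ev_interaction_call <- function(x, ...) {
  cat(sprintf("interaction call [%s]: best score %.3f -> %s\n",
              x$pair_id, x$best_score, x$label))
  invisible(x)
}

#' Write a contact prediction table
#'
#' Tab-separated table (pos_a, pos_b, raw_ec, q_raw, evcomplex_score,
#' rank, plus alignment columns i, j).
#'
#' @param predictions Ranked prediction data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_table <- function(predictions, path) {
  cols <- intersect(c("pos_a", "pos_b", "i", "j", "raw_ec", "q_raw",
                      "evcomplex_score", "rank"), names(predictions))
  utils::write.table(format(predictions[, cols, drop = FALSE], digits = 10,
                            trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
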