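#' Amino-acid alphabet encoding
#'
#' The Potts model is defined over a q-state alphabet. The production
#' default is q = 21: the gap symbol plus the 20 standard amino acids.
#' Reduced alphabets (the first q symbols of the full ordering) are
#' supported for simulation studies where a smaller state space keeps the
#' inference problem small. The gap symbol always occupies state 1, so
#' gauge fixing and gap-excluding coupling norms can refer to a fixed
#' index.
#'
#' @param q Number of states, between 2 and 21.
#' @return An object of class `ev_alphabet` with elements `symbols`
#'   (ordered character vector, gap first), `lookup` (named integer vector
#'   mapping symbol to state), `gap_index` (always 1) and `q`.
#' @examples
#' ab <- aa_alphabet()
#' ab$symbols[ab$gap_index]
#' @export
aa_alphabet <- function(q = 21L) {
  full <- c("-", "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  q <- as.integer(q)
  if (is.na(q) || q < 2L || q > length(full)) {
    stop("alphabet size q must be between 2 and ", length(full))
  }
  symbols <- full[seq_len(q)]
  lookup <- stats::setNames(seq_len(q), symbols)
  structure(list(symbols = symbols, lookup = lookup,
                 gap_index = 1L, q = q),
            class = "ev_alphabet")
}

# Symbols with no slot in the 21-state model: ambiguity/rare codes and the
# insert-state gap. All are mapped to the gap state (least informative).
.nonstandard_symbols <- c("B", "J", "O", "U", "X", "Z", ".", "*")

#' Canonicalize alignment symbols
#'
#' Uppercases all residue symbols and maps non-standard codes (B, J, O, U,
#' X, Z), the insert-state gap "." and "*" to the gap symbol "-". Any
#' remaining symbol outside the 21-state alphabet is also mapped to gap.
#' The operation is idempotent.
#'
#' @param x Character matrix (or vector) of single-character symbols.
#' @return Object of the same shape with canonical symbols.
#' @export
canonicalize_symbols <- function(x) {
  d <- dim(x)
  y <- toupper(as.character(x))
  full <- aa_alphabet(21L)$symbols
  y[!(y %in% full)] <- "-"
  dim(y) <- d
  y
}

#' Encode an alignment as integer states
#'
#' @param x An `ev_alignment`/`ev_concat` object or a character matrix of
#'   canonical symbols.
#' @param alphabet An `ev_alphabet`. Symbols absent from a reduced
#'   alphabet are encoded as the gap state.
#' @return Integer matrix (N x L) with entries in `1..q`.
#' @export
encode_alignment <- function(x, alphabet = aa_alphabet()) {
  m <- if (is.matrix(x)) x else x$matrix
  m <- canonicalize_symbols(m)
  enc <- alphabet$lookup[m]
  enc[is.na(enc)] <- alphabet$gap_index
  matrix(as.integer(enc), nrow = nrow(m), ncol = ncol(m))
}

#' Decode an integer state matrix back to symbols
#'
#' @param enc Integer matrix with entries in `1..q`.
#' @param alphabet An `ev_alphabet`.
#' @return Character matrix of symbols.
#' @export
decode_alignment <- function(enc, alphabet = aa_alphabet()) {
  if (any(enc < 1L | enc > alphabet$q)) {
    stop("encoded states outside 1..q")
  }
  matrix(alphabet$symbols[enc], nrow = nrow(enc), ncol = ncol(enc))
}
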