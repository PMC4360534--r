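#' Potts model container
#'
#' A global maximum-entropy sequence model with single-site fields
#' `h[i, a]` (L x q) and pairwise couplings `J[i, j, a, b]`
#' (L x L x q x q). Couplings satisfy `J[i, j, a, b] == J[j, i, b, a]`
#' and the diagonal blocks `J[i, i, , ]` are zero.
#'
#' @param h Numeric L x q matrix of fields.
#' @param J Numeric L x L x q x q coupling array.
#' @param lambda_h,lambda_J L2 regularization strengths used when the
#'   model is scored or fitted.
#' @return An object of class `ev_potts`.
#' @export
potts_model <- function(h, J, lambda_h = 0.01, lambda_J = NULL) {
  stopifnot(is.matrix(h), length(dim(J)) == 4L)
  L <- nrow(h); q <- ncol(h)
  stopifnot(all(dim(J) == c(L, L, q, q)))
  if (!all(is.finite(h)) || !all(is.finite(J))) stop("non-finite parameters")
  if (max(abs(J - aperm(J, c(2L, 1L, 4L, 3L)))) > 1e-8) {
    stop("couplings must satisfy J[i,j,a,b] == J[j,i,b,a]")
  }
  for (i in seq_len(L)) {
    if (any(J[i, i, , ] != 0)) stop("diagonal coupling blocks must be zero")
  }
  structure(list(h = h, J = J, L = L, q = q,
                 lambda_h = lambda_h,
                 lambda_J = lambda_J %||% 0.01 * (L - 1)),
            class = "ev_potts")
}

#' @export
print.ev_potts <- function(x, ...) {
  cat(sprintf("ev_potts: L = %d sites, q = %d states\n", x$L, x$q))
  invisible(x)
}

as_weight_vector <- function(weights, n) {
  w <- if (inherits(weights, "ev_seqweights")) weights$weights else weights
  if (length(w) != n) stop("weights length must equal number of sequences")
  as.numeric(w)
}

# q x (L*q) coupling slab for site r: column (j-1)*q + b holds J[r, j, , b].
site_coupling_slab <- function(J, r, L, q) {
  slab <- aperm(J[r, , , , drop = FALSE][1L, , , ], c(2L, 3L, 1L))
  dim(slab) <- c(q, q * L)
  slab
}

one_hot_matrix <- function(enc, q) {
  n <- nrow(enc); L <- ncol(enc)
  Z <- matrix(0, n, L * q)
  Z[cbind(rep(seq_len(n), L),
          as.vector(t(t(enc) + (seq_len(L) - 1L) * q)))] <- 1
  Z
}

#' Weighted negative log-pseudolikelihood and its gradient
#'
#' The pseudolikelihood replaces the intractable full likelihood by the
#' product over sites of the conditional multinomial likelihood of each
#' column given the rest of the sequence. This function evaluates the
#' sequence-weighted negative log-pseudolikelihood of an encoded
#' alignment under a Potts model, adds the L2 penalties
#' `n_eff * (lambda_h * ||h||^2 + lambda_J * sum_{i<j} ||J_ij||^2)`,
#' and returns the exact analytic gradient with respect to the fields and
#' the free (symmetric) coupling parameters.
#'
#' @param model An `ev_potts`.
#' @param encoded Integer N x L matrix with entries in `1..q`.
#' @param weights An `ev_seqweights` or numeric vector of length N.
#' @return List with `value` (scalar objective), `grad_h` (L x q) and
#'   `grad_J` (L x L x q x q, symmetric with zero diagonal blocks; entry
#'   `[i, j, a, b]` is the full derivative with respect to the free
#'   parameter `J[i, j, a, b] == J[j, i, b, a]`).
#' @export
pseudolikelihood <- function(model, encoded, weights) {
  L <- model$L; q <- model$q
  if (ncol(encoded) != L) stop("encoded width does not match model L")
  if (max(encoded) > q || min(encoded) < 1L) stop("states outside 1..q")
  n <- nrow(encoded)
  w <- as_weight_vector(weights, n)
  n_eff <- sum(w)
  Z <- one_hot_matrix(encoded, q)
  value <- 0
  grad_h <- matrix(0, L, q)
  site_G <- vector("list", L)
  for (r in seq_len(L)) {
    slab <- site_coupling_slab(model$J, r, L, q)
    E <- Z %*% t(slab)
    E <- sweep(E, 2L, model$h[r, ], "+")
    M <- apply(E, 1L, max)
    P <- exp(E - M)
    Ps <- rowSums(P)
    y <- encoded[, r]
    value <- value - sum(w * (E[cbind(seq_len(n), y)] - M - log(Ps)))
    P <- P / Ps
    R <- P
    R[cbind(seq_len(n), y)] <- R[cbind(seq_len(n), y)] - 1
    R <- R * w
    grad_h[r, ] <- colSums(R)
    site_G[[r]] <- crossprod(Z, R)  # (L*q) x q
  }
  # penalties (sum(J^2)/2 counts each unordered block once)
  value <- value + n_eff * (model$lambda_h * sum(model$h^2) +
                              model$lambda_J * sum(model$J^2) / 2)
  grad_h <- grad_h + 2 * n_eff * model$lambda_h * model$h
  grad_J <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1L)) {
    Gi <- site_G[[i]]
    for (j in seq(i + 1L, L)) {
      # site-i part: Gi[(j-1)q + b, a] = d/dJ[i,j,a,b]
      gi <- t(Gi[(j - 1L) * q + seq_len(q), , drop = FALSE])
      Gj <- site_G[[j]]
      gj <- Gj[(i - 1L) * q + seq_len(q), , drop = FALSE]  # [a, b]
      g <- gi + gj + 2 * n_eff * model$lambda_J * model$J[i, j, , ]
      grad_J[i, j, , ] <- g
      grad_J[j, i, , ] <- t(g)
    }
  }
  list(value = value, grad_h = grad_h, grad_J = grad_J, n_eff = n_eff)
}

#' Per-site conditional probabilities under a Potts model
#'
#' The conditional distribution of each column given the remaining
#' columns of every sequence: the quantities whose product defines the
#' pseudolikelihood. Gauge transformations leave these conditionals
#' unchanged.
#'
#' @inheritParams pseudolikelihood
#' @return List of L matrices (N x q) of conditional probabilities.
#' @export
site_conditionals <- function(model, encoded) {
  L <- model$L; q <- model$q
  Z <- one_hot_matrix(encoded, q)
  lapply(seq_len(L), function(r) {
    E <- Z %*% t(site_coupling_slab(model$J, r, L, q))
    E <- sweep(E, 2L, model$h[r, ], "+")
    P <- exp(E - apply(E, 1L, max))
    P / rowSums(P)
  })
}

#' Fit a Potts model by pseudolikelihood maximization
#'
#' Asymmetric PLM: each site's conditional multinomial regression is
#' maximized independently (a convex problem), and the two estimates of
#' every coupling block are then symmetrized by averaging,
#' `J_ij <- (J_ij + t(J_ji)) / 2`. Optimization is deterministic:
#' L-BFGS-B from a zero initialization with a projected-gradient
#' tolerance `tol`, so identical inputs reproduce identical parameters.
#'
#' @param encoded Integer N x L alignment matrix with entries in `1..q`.
#' @param weights An `ev_seqweights` or numeric vector of length N.
#' @param lambda_h Field regularization (default 0.01).
#' @param lambda_J Coupling regularization (default `0.01 * (L - 1)`).
#'   Both penalties are scaled by `n_eff` in the objective.
#' @param tol Gradient tolerance passed to the optimizer (default 1e-4).
#' @param max_iter Maximum optimizer iterations per site (default 500).
#' @param q Number of states; defaults to the largest state observed.
#' @return An `ev_potts` with attribute `convergence` (per-site optim
#'   codes; non-convergence raises a warning with diagnostics, not an
#'   error) and attribute `n_eff`.
#' @export
fit_plm <- function(encoded, weights, lambda_h = 0.01, lambda_J = NULL,
                    tol = 1e-4, max_iter = 500L, q = NULL) {
  n <- nrow(encoded); L <- ncol(encoded)
  if (n < 2L || L < 2L) stop("need at least 2 sequences and 2 columns")
  q <- as.integer(q %||% max(encoded))
  if (min(encoded) < 1L || max(encoded) > q) stop("states outside 1..q")
  w <- as_weight_vector(weights, n)
  n_eff <- sum(w)
  lambda_J <- lambda_J %||% 0.01 * (L - 1)
  stopifnot(lambda_h > 0, lambda_J > 0)
  Z <- one_hot_matrix(encoded, q)
  h <- matrix(0, L, q)
  J_asym <- array(0, dim = c(L, L, q, q))
  conv <- integer(L)
  for (r in seq_len(L)) {
    block <- (r - 1L) * q + seq_len(q)
    Xr <- Z[, -block, drop = FALSE]
    y <- encoded[, r]
    Y <- matrix(0, n, q)
    Y[cbind(seq_len(n), y)] <- 1
    p <- ncol(Xr)
    fn <- function(par) {
      hr <- par[seq_len(q)]
      W <- matrix(par[-seq_len(q)], p, q)
      E <- Xr %*% W
      E <- sweep(E, 2L, hr, "+")
      M <- apply(E, 1L, max)
      lse <- M + log(rowSums(exp(E - M)))
      -sum(w * (E[cbind(seq_len(n), y)] - lse)) +
        n_eff * (lambda_h * sum(hr^2) + lambda_J * sum(W^2))
    }
    gr <- function(par) {
      hr <- par[seq_len(q)]
      W <- matrix(par[-seq_len(q)], p, q)
      E <- Xr %*% W
      E <- sweep(E, 2L, hr, "+")
      P <- exp(E - apply(E, 1L, max))
      P <- P / rowSums(P)
      R <- (P - Y) * w
      c(colSums(R) + 2 * n_eff * lambda_h * hr,
        as.vector(crossprod(Xr, R)) + 2 * n_eff * lambda_J * as.vector(W))
    }
    fit <- stats::optim(rep(0, q + p * q), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, pgtol = tol,
                                       factr = 1e7))
    conv[r] <- fit$convergence
    h[r, ] <- fit$par[seq_len(q)]
    W <- matrix(fit$par[-seq_len(q)], p, q)
    other <- setdiff(seq_len(L), r)
    for (jj in seq_along(other)) {
      # W rows (jj-1)*q + b, columns a  ->  J[r, j, a, b]
      J_asym[r, other[jj], , ] <-
        t(W[(jj - 1L) * q + seq_len(q), , drop = FALSE])
    }
  }
  if (any(conv != 0L)) {
    warning(sprintf(
      "PLM optimizer did not fully converge at %d/%d sites (codes: %s)",
      sum(conv != 0L), L, paste(unique(conv[conv != 0L]), collapse = ",")))
  }
  J <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      Jij <- (J_asym[i, j, , ] + t(J_asym[j, i, , ])) / 2
      J[i, j, , ] <- Jij
      J[j, i, , ] <- t(Jij)
    }
  }
  model <- potts_model(h, J, lambda_h = lambda_h, lambda_J = lambda_J)
  attr(model, "convergence") <- conv
  attr(model, "n_eff") <- n_eff
  model
}

#' Transform a Potts model to the zero-sum gauge
#'
#' Removes the model's parameter redundancy: every coupling block is
#' double-centered so its rows and columns sum to zero, and the fields
#' absorb the removed row means. The full sequence probabilities — and
#' therefore the per-site conditionals — are unchanged; only the
#' parameter values (and hence coupling norms) change.
#'
#' @param model An `ev_potts`.
#' @return An `ev_potts` in the zero-sum gauge.
#' @export
zero_sum_gauge <- function(model) {
  L <- model$L; q <- model$q
  h <- model$h
  J <- model$J
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      K <- J[i, j, , ]
      rm_ <- rowMeans(K); cm_ <- colMeans(K); mm <- mean(K)
      Kc <- K - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + mm
      J[i, j, , ] <- Kc
      J[j, i, , ] <- t(Kc)
      h[i, ] <- h[i, ] + (rm_ - mm)
      h[j, ] <- h[j, ] + (cm_ - mm)
    }
  }
  out <- potts_model(h, J, lambda_h = model$lambda_h,
                     lambda_J = model$lambda_J)
  attr(out, "n_eff") <- attr(model, "n_eff")
  out
}

#' Reduce a Potts model to a coupling-score matrix
#'
#' Each coupling block is transformed to the zero-sum gauge and summarized
#' by the Frobenius norm over its non-gap (q-1) x (q-1) sub-block (or the
#' full q x q block when `exclude_gap = FALSE`), yielding a symmetric,
#' non-negative L x L score matrix with zero diagonal. The average
#' product correction is not yet applied; see [apply_apc()].
#'
#' @param model A fitted `ev_potts`.
#' @param boundary Optional concatenation boundary (column count of
#'   protein A) recorded for inter/intra bookkeeping downstream.
#' @param exclude_gap Drop the gap state before taking the norm
#'   (default TRUE).
#' @return An object of class `ev_couplings` with fields `scores`,
#'   `boundary`, `apc_applied = FALSE`.
#' @export
coupling_scores <- function(model, boundary = NULL, exclude_gap = TRUE) {
  L <- model$L; q <- model$q
  scores <- matrix(0, L, L)
  idx <- if (exclude_gap && q > 2L) seq(2L, q) else seq_len(q)
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      K <- model$J[i, j, , ]
      rm_ <- rowMeans(K); cm_ <- colMeans(K); mm <- mean(K)
      Kc <- K - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + mm
      scores[i, j] <- scores[j, i] <- sqrt(sum(Kc[idx, idx]^2))
    }
  }
  new_couplings(scores, boundary = boundary, apc_applied = FALSE)
}

new_couplings <- function(scores, boundary = NULL, apc_applied = FALSE) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  if (max(abs(scores - t(scores))) > 1e-10) stop("scores must be symmetric")
  if (!is.null(boundary)) {
    boundary <- as.integer(boundary)
    stopifnot(boundary > 0L, boundary < nrow(scores))
  }
  structure(list(scores = scores, boundary = boundary,
                 apc_applied = apc_applied, L = nrow(scores)),
            class = "ev_couplings")
}

#' @export
print.ev_couplings <- function(x, ...) {
  cat(sprintf("ev_couplings: %d x %d (boundary: %s, APC: %s)\n",
              x$L, x$L, x$boundary %||% "none",
              if (x$apc_applied) "applied" else "raw"))
  invisible(x)
}

#' Average product correction
#'
#' Subtracts the background `mean_i * mean_j / mean_all` from every entry
#' of a symmetric coupling-score matrix, yielding roughly zero-mean
#' corrected scores (which may be negative). By default the row and
#' overall means are computed over off-diagonal entries, the convention
#' for coupling matrices whose diagonal is identically zero; with
#' `exclude_diagonal = FALSE` the means run over all entries, in which
#' case the correction annihilates exactly-rank-one matrices.
#' A constant matrix maps to zero either way, and an all-zero matrix is
#' returned unchanged.
#'
#' @param m An `ev_couplings` or a symmetric numeric matrix.
#' @param exclude_diagonal Compute means over off-diagonal entries only
#'   (default TRUE).
#' @return Corrected object of the same type (diagonal kept at zero for
#'   `ev_couplings` input).
#' @export
apply_apc <- function(m, exclude_diagonal = TRUE) {
  is_cpl <- inherits(m, "ev_couplings")
  mat <- if (is_cpl) m$scores else m
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- nrow(mat)
  if (all(mat == 0)) {
    return(if (is_cpl) {
      m$apc_applied <- TRUE
      m
    } else mat)
  }
  if (exclude_diagonal && n > 1L) {
    row_means <- (rowSums(mat) - diag(mat)) / (n - 1L)
    mean_all <- (sum(mat) - sum(diag(mat))) / (n * (n - 1L))
  } else {
    row_means <- rowMeans(mat)
    mean_all <- mean(mat)
  }
  corrected <- mat - outer(row_means, row_means) / mean_all
  if (is_cpl) {
    diag(corrected) <- 0
    m$scores <- corrected
    m$apc_applied <- TRUE
    m
  } else {
    corrected
  }
}

#' Export coupling scores as an edge list
#'
#' Long-format table of all residue pairs with their raw and
#' APC-corrected scores and an intra/inter label, in focus-sequence
#' numbering when column maps are available.
#'
#' @param raw An `ev_couplings` before APC.
#' @param corrected The same matrix after [apply_apc()].
#' @param column_maps Optional list with elements `a` and `b` mapping
#'   alignment columns to focus residue numbers (as in `ev_concat`).
#' @return Data.frame with columns i, j, pos_a, pos_b, block, raw_score,
#'   apc_score, sorted by descending apc_score.
#' @export
coupling_edge_list <- function(raw, corrected, column_maps = NULL) {
  stopifnot(inherits(raw, "ev_couplings"), inherits(corrected, "ev_couplings"))
  L <- raw$L
  b <- raw$boundary
  ut <- which(upper.tri(raw$scores), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  block <- if (is.null(b)) {
    rep("intra", length(i))
  } else {
    ifelse(j <= b, "intra_a", ifelse(i > b, "intra_b", "inter"))
  }
  pos_of <- function(k) {
    if (is.null(column_maps) || is.null(b)) return(k)
    ifelse(k <= b, column_maps$a[k],
           column_maps$b[pmax(k - b, 1L)])
  }
  df <- data.frame(i = i, j = j,
                   pos_a = pos_of(i), pos_b = pos_of(j),
                   block = block,
                   raw_score = raw$scores[ut],
                   apc_score = corrected$scores[ut])
  df[order(-df$apc_score, df$i, df$j), , drop = FALSE]
}
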