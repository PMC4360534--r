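random_potts <- function(L, q, sd = 0.3, lambda_h = 0.01, lambda_J = 0.05,
                         seed = 1) {
  set.seed(seed)
  h <- matrix(rnorm(L * q, sd = sd), L, q)
  J <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      K <- matrix(rnorm(q * q, sd = sd), q, q)
      J[i, j, , ] <- K
      J[j, i, , ] <- t(K)
    }
  }
  potts_model(h, J, lambda_h = lambda_h, lambda_J = lambda_J)
}

test_that("zero-parameter pseudolikelihood reduces to uniform conditionals", {
  set.seed(2)
  L <- 5; q <- 4; N <- 40
  enc <- matrix(sample.int(q, N * L, TRUE), N, L)
  w <- runif(N, 0.2, 1)
  m0 <- potts_model(matrix(0, L, q), array(0, dim = c(L, L, q, q)))
  val <- pseudolikelihood(m0, enc, w)$value
  expect_equal(val, L * sum(w) * log(q))
  # linearity: doubling all weights doubles the (penalty-free) data term
  expect_equal(pseudolikelihood(m0, enc, 2 * w)$value, 2 * val)
})

test_that("analytic pseudolikelihood gradient matches finite differences", {
  L <- 4; q <- 3; N <- 30
  model <- random_potts(L, q, seed = 8)
  set.seed(9)
  enc <- matrix(sample.int(q, N * L, TRUE), N, L)
  w <- runif(N, 0.2, 1)
  g <- pseudolikelihood(model, enc, w)
  eps <- 1e-5
  f_at <- function(m) pseudolikelihood(m, enc, w)$value
  for (i in 1:L) {
    for (a in 1:q) {
      mp <- model; mp$h[i, a] <- mp$h[i, a] + eps
      mm <- model; mm$h[i, a] <- mm$h[i, a] - eps
      expect_equal(g$grad_h[i, a], (f_at(mp) - f_at(mm)) / (2 * eps),
                   tolerance = 1e-6)
    }
  }
  set.seed(10)
  for (k in 1:15) {  # random subset of coupling parameters
    i <- sample(L - 1, 1)
    js <- seq(i + 1, L)
    j <- js[sample.int(length(js), 1)]
    a <- sample(q, 1); b <- sample(q, 1)
    mp <- model
    mp$J[i, j, a, b] <- mp$J[i, j, a, b] + eps
    mp$J[j, i, b, a] <- mp$J[j, i, b, a] + eps
    mm <- model
    mm$J[i, j, a, b] <- mm$J[i, j, a, b] - eps
    mm$J[j, i, b, a] <- mm$J[j, i, b, a] - eps
    expect_equal(g$grad_J[i, j, a, b], (f_at(mp) - f_at(mm)) / (2 * eps),
                 tolerance = 1e-6)
  }
})

test_that("gauge fixing changes parameters but not conditional probabilities", {
  L <- 4; q <- 3; N <- 20
  model <- random_potts(L, q, seed = 21)
  set.seed(22)
  enc <- matrix(sample.int(q, N * L, TRUE), N, L)
  gauged <- zero_sum_gauge(model)
  # zero-sum property of every transformed block
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    expect_lt(max(abs(rowSums(gauged$J[i, j, , ]))), 1e-12)
    expect_lt(max(abs(colSums(gauged$J[i, j, , ]))), 1e-12)
  }
  expect_gt(max(abs(gauged$J - model$J)), 1e-3)
  p0 <- site_conditionals(model, enc)
  p1 <- site_conditionals(gauged, enc)
  for (r in 1:L) {
    expect_lt(max(abs(p0[[r]] - p1[[r]])), 1e-10)
  }
})

test_that("PLM fitting is deterministic", {
  set.seed(33)
  enc <- matrix(sample.int(3, 25 * 6, TRUE), 25, 6)
  w <- rep(1, 25)
  m1 <- fit_plm(enc, w, q = 3)
  m2 <- fit_plm(enc, w, q = 3)
  expect_identical(m1$h, m2$h)
  expect_identical(m1$J, m2$J)
})

test_that("independent uniform columns yield only residual coupling scores", {
  set.seed(44)
  enc <- matrix(sample.int(4, 400 * 8, TRUE), 400, 8)
  # strong coupling penalty: with no signal the regularizer must win
  model <- fit_plm(enc, rep(1, 400), lambda_J = 1, q = 4)
  scores <- coupling_scores(model)$scores
  # no signal: the regularizer keeps every score far below the planted
  # scale (strength 3) used in recovery experiments
  expect_lt(max(scores), 0.05 * 3)
})

test_that("coupling scores isolate the nonzero block and match a direct oracle", {
  L <- 5; q <- 4
  J <- array(0, dim = c(L, L, q, q))
  expect_equal(max(coupling_scores(
    potts_model(matrix(0, L, q), J))$scores), 0)
  set.seed(55)
  K <- matrix(rnorm(q * q), q, q)
  J[2, 4, , ] <- K
  J[4, 2, , ] <- t(K)
  cpl <- coupling_scores(potts_model(matrix(0, L, q), J))
  nz <- which(cpl$scores != 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]), c("2 4", "4 2"))
  # direct gauge + norm recomputation
  Kc <- K - outer(rowMeans(K), rep(1, q)) -
    outer(rep(1, q), colMeans(K)) + mean(K)
  expect_equal(cpl$scores[2, 4], sqrt(sum(Kc[-1, -1]^2)))
  full <- coupling_scores(potts_model(matrix(0, L, q), J),
                          exclude_gap = FALSE)
  expect_equal(full$scores[2, 4], sqrt(sum(Kc^2)))
  # symmetry and zero diagonal always hold
  expect_identical(cpl$scores, t(cpl$scores))
  expect_equal(diag(cpl$scores), rep(0, L))
})

test_that("random coupling matrices match the gauge+norm oracle on a fitted model", {
  model <- random_potts(4, 3, seed = 66)
  cpl <- coupling_scores(model, exclude_gap = TRUE)
  q <- 3
  for (i in 1:3) for (j in (i + 1):4) {
    K <- model$J[i, j, , ]
    Kc <- K - outer(rowMeans(K), rep(1, q)) -
      outer(rep(1, q), colMeans(K)) + mean(K)
    expect_equal(cpl$scores[i, j], sqrt(sum(Kc[-1, -1]^2)))
  }
})

test_that("average product correction obeys its algebraic identities", {
  n <- 6
  cm <- matrix(5, n, n)
  expect_lt(max(abs(apply_apc(cm))), 1e-12)
  expect_lt(max(abs(apply_apc(cm, exclude_diagonal = FALSE))), 1e-12)
  set.seed(77)
  u <- runif(n, 0.5, 2)
  expect_lt(max(abs(apply_apc(outer(u, u), exclude_diagonal = FALSE))),
            1e-10)
  m <- matrix(rnorm(n * n), n, n)
  m <- abs(m + t(m))
  expect_equal(apply_apc(m), bf_apc(m), tolerance = 1e-12)
  expect_equal(apply_apc(m, exclude_diagonal = FALSE),
               bf_apc(m, exclude_diagonal = FALSE), tolerance = 1e-12)
  zed <- matrix(0, n, n)
  expect_identical(apply_apc(zed), zed)
})

test_that("edge list labels intra and inter blocks in focus numbering", {
  L <- 5
  s <- matrix(0, L, L)
  s[1, 4] <- s[4, 1] <- 2     # inter (boundary 3)
  s[1, 2] <- s[2, 1] <- 1     # intra_a
  s[4, 5] <- s[5, 4] <- 0.5   # intra_b
  raw <- evcomplexr:::new_couplings(s, boundary = 3L)
  edges <- coupling_edge_list(raw, raw,
                              column_maps = list(a = c(10L, 11L, 12L),
                                                 b = c(40L, 41L)))
  expect_equal(nrow(edges), choose(L, 2))
  top <- edges[1, ]
  expect_equal(top$block, "inter")
  expect_equal(c(top$pos_a, top$pos_b), c(10L, 40L))
  expect_equal(edges$block[edges$i == 1 & edges$j == 2], "intra_a")
  expect_equal(edges$block[edges$i == 4 & edges$j == 5], "intra_b")
})
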