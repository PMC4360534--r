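inter_df <- function(scores) {
  data.frame(i = seq_along(scores), j = seq_along(scores) + 10L,
             pos_a = seq_along(scores), pos_b = seq_along(scores),
             raw_ec = scores)
}

test_that("raw reliability is the ratio to the absolute minimum inter score", {
  out <- raw_reliability(inter_df(c(2.0, 1.0, -0.5)))
  expect_equal(out$q_raw, c(4.0, 2.0, -1.0))
  # scale invariance under positive rescaling
  out10 <- raw_reliability(inter_df(10 * c(2.0, 1.0, -0.5)))
  expect_equal(out10$q_raw, out$q_raw)
  # the minimum-attaining pair always lands at -1
  set.seed(3)
  for (k in 1:10) {
    sc <- rnorm(20)
    if (min(sc) >= 0) next
    qr <- raw_reliability(inter_df(sc))$q_raw
    expect_equal(qr[which.min(sc)], -1)
  }
})

test_that("an all-positive inter block leaves the background width undefined", {
  expect_error(raw_reliability(inter_df(c(0.5, 1, 2))),
               "background width undefined")
  expect_error(raw_reliability(inter_df(numeric(0))), "empty")
})

test_that("EVcomplex normalization follows the closed-form depth factor", {
  d <- inter_df(c(2.0, 1.0, -0.5))
  d <- raw_reliability(d)
  # N_eff/L = 1 -> denominator 2
  s1 <- evcomplex_scores(d, n_eff = 50, L = 50)
  expect_equal(s1$evcomplex_score[s1$q_raw == 4.0], 2.0)
  # N_eff/L = 0.25 -> (0.25)^(-1/2) = 2 -> denominator 3
  s2 <- evcomplex_scores(d, n_eff = 25, L = 100)
  expect_equal(s2$evcomplex_score[s2$q_raw == 4.0], 4.0 / 3)
  q16 <- evcomplex_scores(raw_reliability(inter_df(c(1.6 * 0.5, -0.5))),
                          n_eff = 25, L = 100)
  expect_equal(q16$evcomplex_score[q16$q_raw == 1.6], 1.6 / 3)
  # ranking is by descending score
  expect_equal(s1$rank, seq_len(nrow(s1)))
  expect_true(all(diff(s1$evcomplex_score) <= 0))
})

test_that("EVcomplex score is monotone in q_raw and in alignment depth", {
  d <- raw_reliability(inter_df(c(3, 2, 1, -1)))
  s <- evcomplex_scores(d, n_eff = 40, L = 50)
  ord <- order(-s$q_raw)
  expect_equal(s$q_raw[ord], sort(s$q_raw, decreasing = TRUE))
  # deeper alignments increase every positive score towards q_raw
  shallow <- evcomplex_scores(d, n_eff = 10, L = 50)
  deep <- evcomplex_scores(d, n_eff = 5000, L = 50)
  pos <- d$q_raw > 0
  expect_true(all(deep$evcomplex_score[match(d$q_raw[pos], deep$q_raw)] >
                    shallow$evcomplex_score[match(d$q_raw[pos],
                                                  shallow$q_raw)]))
  expect_true(all(deep$evcomplex_score[deep$q_raw > 0] <
                    deep$q_raw[deep$q_raw > 0]))
})

test_that("rescaling raw inter scores leaves EVcomplex scores unchanged", {
  set.seed(5)
  sc <- rnorm(30)
  base <- evcomplex_scores(raw_reliability(inter_df(sc)), 80, 60)
  for (c_ in c(0.01, 3, 1000)) {
    scaled <- evcomplex_scores(raw_reliability(inter_df(c_ * sc)), 80, 60)
    expect_equal(scaled$evcomplex_score, base$evcomplex_score)
  }
})

test_that("sequence sufficiency is a strict ratio threshold", {
  expect_true(sufficiency_check(31, 100))
  expect_false(sufficiency_check(30, 100))
  expect_true(sufficiency_check(1.9 * 300, 300))   # MetN:MetI-like depth
  expect_true(sufficiency_check(95.4 * 300, 300))  # KdpD:CheY-like depth
  expect_false(sufficiency_check(0.2 * 300, 300))
})

test_that("contact selection keeps the 0.8 boundary and matches a filter oracle", {
  d <- data.frame(pos_a = 1:3, pos_b = 4:6, q_raw = c(1, 2, 3),
                  evcomplex_score = c(0.85, 0.80, 0.79))
  sel <- select_contacts(d)
  expect_equal(sort(sel$evcomplex_score), c(0.80, 0.85))
  set.seed(6)
  for (k in 1:10) {
    n <- sample(5:30, 1)
    rd <- data.frame(pos_a = sample(50, n, TRUE),
                     pos_b = sample(50, n, TRUE),
                     evcomplex_score = round(rnorm(n, 0.7, 0.3), 3))
    sel <- select_contacts(rd)
    want <- rd[rd$evcomplex_score >= 0.8, ]
    expect_setequal(paste(sel$pos_a, sel$pos_b, sel$evcomplex_score),
                    paste(want$pos_a, want$pos_b, want$evcomplex_score))
    expect_true(all(diff(sel$evcomplex_score) <= 0))
  }
  expect_equal(nrow(select_contacts(d[0, ])), 0L)
})

test_that("subunit classification follows the 0.8/0.75 bands", {
  expect_equal(classify_interaction(0.85)$label, "interacting")
  expect_equal(classify_interaction(0.80)$label, "interacting")
  expect_equal(classify_interaction(0.77)$label, "weak")
  expect_equal(classify_interaction(0.75)$label, "weak")
  expect_equal(classify_interaction(0.70)$label, "rejected")
  # a non-empty contact selection can never coincide with a rejection
  cfg <- scoring_config()
  d <- data.frame(pos_a = 1, pos_b = 2, evcomplex_score = 0.9)
  sel <- select_contacts(d, cfg)
  expect_gt(nrow(sel), 0)
  expect_false(classify_interaction(max(d$evcomplex_score),
                                    cfg)$label == "rejected")
})

test_that("scoring configuration validates its threshold ordering", {
  expect_error(scoring_config(contact_threshold = 0.7, weak_lower = 0.75))
  cfg <- scoring_config(contact_threshold = 0.9, weak_lower = 0.85)
  expect_equal(classify_interaction(0.87, cfg)$label, "weak")
})
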