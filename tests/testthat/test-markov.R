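test_that("transition estimation matches direct counts", {
  s <- symbolic_sequence(c("A", "A", "A", "B"), labels = LETTERS[1:4])
  m <- suppressWarnings(estimate_transition_matrix(s))
  expect_equal(unname(m$P["A", ]), c(2 / 3, 1 / 3, 0, 0))
  expect_equal(unname(m$initial), c(3 / 4, 1 / 4, 0, 0))
  # pooling two copies leaves the ratios unchanged
  m2 <- suppressWarnings(estimate_transition_matrix(list(s, s)))
  expect_equal(m2$P, m$P)
  expect_error(estimate_transition_matrix(list()), "at least one")
})

test_that("states without outgoing transitions get a flagged uniform row", {
  const <- symbolic_sequence(rep("A", 10), labels = LETTERS[1:4])
  expect_warning(m <- estimate_transition_matrix(const), "uniform row")
  expect_equal(unname(m$P["A", ]), c(1, 0, 0, 0))
  expect_setequal(m$zero_rows, 1:3)
  for (i in 2:4) expect_equal(unname(m$P[i, ]), rep(0.25, 4))
})

test_that("surrogates are deterministic given the seed and reproduce bounds", {
  m <- diagonal_markov_model(4, 0.8)
  a <- synthesize_surrogate(m, 1000, seed = 901)
  b <- synthesize_surrogate(m, 1000, seed = 901)
  expect_identical(a$states, b$states)
  expect_true(all(a$states %in% 0:3))
  # an absorbing identity chain yields a constant sequence
  ident <- transition_model(diag(4), initial = c(0, 0, 1, 0))
  s <- synthesize_surrogate(ident, 50, seed = 902)
  expect_identical(s$states, rep(2L, 50))
  expect_error(synthesize_surrogate(m, 0), "n must be")
})

test_that("re-estimation recovers the generating matrix", {
  m <- diagonal_markov_model(4, 0.9)
  s <- synthesize_surrogate(m, 1e5, seed = 903)
  est <- estimate_transition_matrix(s)
  row_l1 <- apply(abs(est$P - m$P), 1, sum)
  expect_lt(max(row_l1), 0.02)
  # stationary distribution of the estimate is near uniform
  expect_equal(unname(est$stationary), rep(0.25, 4), tolerance = 0.05)
})

test_that("surrogate entropy rate approaches the analytic value", {
  m <- diagonal_markov_model(4, 0.85)
  h_theo <- analytic_markov_entropy_rate(m)
  h_hat <- vapply(1:5, function(i) {
    entropy_rate_excess(synthesize_surrogate(m, 1e5, seed = 910 + i))$h_x
  }, numeric(1))
  expect_lt(abs(mean(h_hat) - h_theo), 0.02)
})

test_that("surrogates of repeat-free sources have zero diagonal", {
  s <- generate_sequence("markov_diagonal", A = 4, n = 20000, d = 0.9,
                         seed = 904)
  j <- jump_sequence(s)
  mj <- estimate_transition_matrix(j)
  expect_equal(unname(diag(mj$P)), rep(0, 4))
  surr <- synthesize_surrogate(mj, length(j$states), seed = 905)
  m2 <- estimate_transition_matrix(surr)
  expect_equal(unname(diag(m2$P)), rep(0, 4))
})

test_that("surrogates preserve lag-0/1 PAI structure but not higher lags", {
  s <- generate_sequence("markov_diagonal", A = 4, n = 30000, d = 0.9,
                         seed = 906)
  surr <- synthesize_surrogate(estimate_transition_matrix(s),
                               length(s$states), seed = 907)
  p_src <- pai(s, 3)
  p_sur <- pai(surr, 3)
  expect_equal(p_sur$pai[p_sur$lag <= 1], p_src$pai[p_src$lag <= 1],
               tolerance = 0.02)
  expect_true(all(p_sur$pai[p_sur$lag >= 2] < 0.02))
})

test_that("tidy and glance summarise transition models", {
  m <- diagonal_markov_model(4, 0.9)
  td <- tidy(m)
  expect_equal(nrow(td), 16)
  expect_equal(td$prob[td$from == "A" & td$to == "A"], 0.9)
  gl <- glance(m)
  expect_equal(gl$diag_mean, 0.9)
  expect_equal(gl$entropy_rate, analytic_markov_entropy_rate(m))
})

test_that("shuffle surrogate keeps the symbol distribution only", {
  s <- generate_sequence("markov_diagonal", A = 4, n = 10000, d = 0.9,
                         seed = 908)
  sh <- shuffle_surrogate(s, seed = 909)
  expect_equal(sort(sh$states), sort(s$states))
  expect_gt(suppressWarnings(entropy_rate_excess(sh)$h_x),
            suppressWarnings(entropy_rate_excess(s)$h_x))
})
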