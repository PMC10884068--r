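entropy_bits_ref <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

test_that("block entropy matches hand-enumerable cases", {
  const <- symbolic_sequence(rep("A", 100), labels = LETTERS[1:4])
  for (k in c(1, 3, 6)) expect_equal(block_entropy(const, k), 0)

  ab <- symbolic_sequence(rep(c("A", "B"), 100), labels = c("A", "B"))
  expect_equal(block_entropy(ab, 1), 1)
  # only the words AB and BA occur, near-equiprobably (199 windows: 100/99)
  expect_equal(block_entropy(ab, 2), entropy_bits_ref(c(100, 99)))

  expect_error(block_entropy(ab, 0), "block length")
  expect_error(block_entropy(ab, 1000), "block length")
})

test_that("block entropy is non-decreasing in k and bounded by k*log2(A)", {
  # monotonicity of the plug-in estimates needs the word distributions to be
  # sampled; restrict k to A^k well below the window count
  withr::local_seed(601)
  for (i in 1:10) {
    s <- random_sequence(sample(2000:20000, 1), sample(2:5, 1))
    A <- length(s$labels)
    ks <- Filter(function(k) A^k <= length(s) / 4, 1:6)
    H <- vapply(ks, function(k) block_entropy(s, k), numeric(1))
    expect_true(all(diff(H) >= -1e-9))
    expect_true(all(H <= ks * log2(A) + 1e-12))
    expect_lte(H[1], log2(A) + 1e-12)
  }
})

test_that("entropy rate fit recovers limiting cases", {
  const <- symbolic_sequence(rep("A", 5000), labels = LETTERS[1:4])
  fit <- entropy_rate_excess(const)
  expect_equal(fit$h_x, 0)
  expect_equal(fit$excess_entropy, 0)

  withr::local_seed(602)
  iid <- random_sequence(1e5, 4)
  fit <- entropy_rate_excess(iid)
  expect_equal(fit$h_x, 2, tolerance = 0.01)
  expect_lt(abs(fit$excess_entropy), 0.05)

  # 2-state chain with p(stay) = 0.9: closed form -(0.9 log2 0.9 + 0.1 log2 0.1)
  m <- diagonal_markov_model(2, 0.9)
  s <- synthesize_surrogate(m, 1e5, seed = 603)
  expect_equal(entropy_rate_excess(s)$h_x,
               -(0.9 * log2(0.9) + 0.1 * log2(0.1)), tolerance = 0.02)

  expect_error(entropy_rate_excess(iid, k_max = 1), "k_max")
  expect_warning(entropy_rate_excess(random_sequence(100, 4)), "biased")
})

test_that("tidy/glance/autoplot expose the block-entropy fit", {
  withr::local_seed(604)
  fit <- suppressWarnings(entropy_rate_excess(random_sequence(3000, 4)))
  td <- tidy(fit)
  expect_named(td, c("k", "H", "fitted", "residual"))
  expect_equal(nrow(td), 6)
  expect_equal(td$H - td$fitted, td$residual)
  gl <- glance(fit)
  expect_equal(gl$h_x, fit$h_x)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("analytic Markov entropy rate matches closed forms", {
  expect_equal(analytic_markov_entropy_rate(diag(2)), 0)
  for (A in c(2, 4, 5)) {
    U <- matrix(1 / A, A, A)
    expect_equal(analytic_markov_entropy_rate(U), log2(A), tolerance = 1e-12)
  }
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  expect_equal(analytic_markov_entropy_rate(P),
               -(0.9 * log2(0.9) + 0.1 * log2(0.1)), tolerance = 1e-12)
  # reducible chain with non-deterministic rows: no unique stationary
  R <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0.5, 0.5),
             c(0, 0, 0.5, 0.5))
  expect_error(analytic_markov_entropy_rate(R), "stationary")
})

test_that("partial autoinformation separates iid, Markov and periodic", {
  withr::local_seed(605)
  iid <- random_sequence(30000, 4)
  p <- pai(iid, 4)
  expect_equal(p$pai[p$lag == 0], 2, tolerance = 0.02)
  # residual positive values at higher lags are pure plug-in estimator bias,
  # which grows with the conditioning-set size
  expect_true(all(p$pai[p$lag >= 1] < 0.03))
  expect_lt(p$pai[p$lag == 1], 0.005)

  ab <- symbolic_sequence(rep(c("A", "B"), 500), labels = c("A", "B"))
  p2 <- pai(ab, 2)
  expect_equal(p2$pai[p2$lag == 0], 1, tolerance = 1e-6)
  expect_equal(p2$pai[p2$lag == 1], 1, tolerance = 0.01)

  mk <- generate_sequence("markov_diagonal", A = 4, n = 30000, d = 0.9,
                          seed = 606)
  p3 <- pai(mk, 5)
  expect_gt(p3$pai[p3$lag == 1], 0.5)   # strong first-order structure
  expect_true(all(p3$pai[p3$lag >= 2] < 0.02))

  expect_true(all(p$pai >= 0) && all(p3$pai >= 0))
  expect_error(pai(ab, 1000), "lag_max")
})
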