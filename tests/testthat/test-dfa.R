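test_that("partition enumeration matches the combinatorics", {
  p4 <- enumerate_partitions(4)
  expect_length(p4, 3)
  keys <- vapply(p4, function(p) paste(sort(p$plus), collapse = ""),
                 character(1))
  expect_setequal(keys, c("01", "02", "03"))  # AB|CD, AC|BD, AD|BC

  expect_length(enumerate_partitions(5), 10)
  expect_length(enumerate_partitions(2), 1)
  # every partition covers the alphabet disjointly
  for (p in enumerate_partitions(5)) {
    expect_identical(sort(c(p$plus, p$minus)), 0:4)
    expect_length(p$plus, 2)
  }
  expect_error(enumerate_partitions(1), ">= 2")
})

test_that("DFA recovers H = 0.5 for uncorrelated series", {
  withr::local_seed(801)
  H <- replicate(5, {
    dfa_fluctuation(sample(c(-1, 1), 30000, replace = TRUE))$H
  })
  expect_equal(mean(H), 0.5, tolerance = 0.05)
})

test_that("DFA slope is invariant under amplitude scaling", {
  withr::local_seed(802)
  w <- sample(c(-1, 1), 10000, replace = TRUE)
  f1 <- dfa_fluctuation(w, scale_max = 2000)
  f2 <- dfa_fluctuation(7.3 * w, scale_max = 2000)
  expect_equal(f1$H, f2$H, tolerance = 1e-10)
  expect_equal(f2$F, 7.3 * f1$F, tolerance = 1e-8)
})

test_that("DFA recovers a known Hurst exponent from the spectral oracle", {
  withr::local_seed(803)
  H_hat <- replicate(4, dfa_fluctuation(fgn_oracle(30000, 0.7))$H)
  expect_equal(mean(H_hat), 0.7, tolerance = 0.05)
})

test_that("degenerate near-constant inputs are flagged, constants undefined", {
  s <- generate_sequence("single_flip", A = 4, n = 20000)
  expect_warning(h <- hurst(s), "degenerate")
  # an isolated step in the walk inflates the exponent far above 1
  expect_gt(h$H_mean, 1)
  const <- rep(1, 20000)
  expect_warning(f <- dfa_fluctuation(const), "degenerate")
  expect_true(is.na(f$H))
  expect_warning(dfa_fluctuation(rnorm(100), scale_max = 2500), "length")
})

test_that("partition-averaged Hurst of iid 4-state sequences is ~0.5", {
  withr::local_seed(804)
  H <- replicate(3, glance(hurst(random_sequence(30000, 4)))$H_mean)
  expect_equal(mean(H), 0.5, tolerance = 0.05)
})

test_that("H is invariant under matched label and partition permutation", {
  withr::local_seed(805)
  s <- generate_sequence("markov_diagonal", A = 4, n = 20000, seed = 806)
  perm <- c(2L, 0L, 3L, 1L)
  relab <- symbolic_sequence(perm[s$states + 1L], labels = s$labels)
  # the permuted sequence under the permuted partition gives the same walk
  w1 <- apply_partition(s, c(0L, 1L), c(2L, 3L))
  w2 <- apply_partition(relab, perm[c(1, 2)], perm[c(3, 4)])
  expect_identical(w1, w2)
  expect_equal(dfa_fluctuation(w1, scale_max = 2000)$H,
               dfa_fluctuation(w2, scale_max = 2000)$H)
  # the partition-averaged exponent is invariant under relabeling
  expect_equal(glance(hurst(s, scale_max = 2000))$H_mean,
               glance(hurst(relab, scale_max = 2000))$H_mean,
               tolerance = 1e-10)
})

test_that("jump sequences of Markov surrogates have no long-range structure", {
  s <- generate_sequence("markov_diagonal", A = 4, n = 30000, d = 0.9,
                         seed = 807)
  j <- jump_sequence(s)
  H <- suppressWarnings(glance(hurst(j, scale_max = floor(length(j) / 4)))$H_mean)
  expect_equal(H, 0.5, tolerance = 0.1)
})

test_that("tidy/glance/autoplot expose the DFA results", {
  withr::local_seed(808)
  f <- dfa_fluctuation(sample(c(-1, 1), 8000, replace = TRUE),
                       scale_max = 2000)
  expect_named(tidy(f), c("scale", "F"))
  expect_true(all(diff(tidy(f)$scale) > 0))
  expect_s3_class(autoplot(f), "ggplot")
  h <- hurst(random_sequence(8000, 4), scale_max = 2000)
  expect_named(tidy(h), c("partition", "H", "degenerate"))
  expect_equal(glance(h)$H_mean, mean(tidy(h)$H))
  expect_s3_class(autoplot(h), "ggplot")
})
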