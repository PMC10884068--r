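test_that("sequence_complexity returns one tidy row with meta columns", {
  s <- generate_sequence("markov_diagonal", A = 4, n = 6000, d = 0.9,
                         seed = 21)
  row <- sequence_complexity(s, scale_max = 1200, quiet = TRUE)
  expect_equal(nrow(row), 1)
  expect_true(all(c("n", "h_x", "excess_entropy", "lzc_rate", "H_mean",
                    "degenerate", "kind", "seed", "d") %in% names(row)))
  expect_equal(row$n, 6000)
  expect_true(all(is.finite(c(row$h_x, row$lzc_rate, row$H_mean))))
  # metric subsets are honoured
  expect_false("H_mean" %in% names(sequence_complexity(s, metrics = "hx")))
})

test_that("a reduced temperature sweep shows the expected phenomenology", {
  sw <- run_temperature_sweep(L = 10, rel_temps = c(0.4, 1.0, 3.0),
                              n_iterations = 3000, warmup = 600,
                              n_nodes = 3, n_runs = 2, seed = 22,
                              scale_max = 700)
  expect_setequal(unique(sw$source), c("model", "surrogate"))
  expect_equal(nrow(sw), 3 * 2 * 3 * 2)
  mh <- sw |> dplyr::filter(source == "model") |>
    dplyr::group_by(rel_temp) |>
    dplyr::summarise(h = mean(h_x), E = mean(excess_entropy))
  expect_true(all(diff(mh$h) > 0))              # entropy rate rises with T
  expect_equal(mh$rel_temp[which.max(mh$E)], 1) # excess entropy peaks at Tc
  # surrogates track the model's entropy rate closely
  diffs <- sw |> dplyr::group_by(rel_temp, run, node) |>
    dplyr::summarise(d = abs(diff(h_x)), .groups = "drop")
  expect_lt(max(diffs$d), 0.1)
})

test_that("sweeps with identical seeds are identical", {
  args <- list(L = 6, rel_temps = c(0.8, 1.6), n_iterations = 600,
               warmup = 100, n_nodes = 2, n_runs = 1, seed = 23,
               scale_min = 16, scale_max = 150, metrics = c("hx", "lzc"))
  expect_identical(do.call(run_temperature_sweep, args),
                   do.call(run_temperature_sweep, args))
})

test_that("convergence study brackets the analytic rate from both sides", {
  m <- diagonal_markov_model(4, 0.9)
  conv <- run_convergence(m, lengths = c(1000, 5000, 30000),
                          n_replicates = 5, seed = 24)
  expect_equal(nrow(conv), 15)
  expect_equal(conv$analytic_rate[1], analytic_markov_entropy_rate(m))
  agg <- conv |> dplyr::group_by(length) |>
    dplyr::summarise(h = mean(h_x), lz = mean(lzc_rate))
  h_theo <- conv$analytic_rate[1]
  expect_true(all(agg$h < h_theo))   # plug-in estimator from below
  expect_true(all(agg$lz > h_theo))  # LZ-76 from above
  # gaps shrink from the shortest to the longest prefix
  expect_lt(agg$lz[3] - h_theo, agg$lz[1] - h_theo)
  expect_lt(h_theo - agg$h[3], h_theo - agg$h[1])
})

test_that("near-deterministic chains give near-zero rates at all lengths", {
  m <- diagonal_markov_model(4, 0.999)
  conv <- run_convergence(m, lengths = c(2000, 10000), n_replicates = 2,
                          seed = 25)
  expect_true(all(conv$h_x < 0.05))
  expect_true(all(conv$lzc_rate < 0.05))
})

test_that("surrogate comparison separates full and jump sequences", {
  s <- generate_sequence("markov_diagonal", A = 4, n = 30000, d = 0.9,
                         seed = 26)
  cmp <- suppressWarnings(
    compare_with_surrogates(s, n_surrogates = 2, seed = 27))
  expect_setequal(unique(cmp$variant), c("full", "jump"))
  expect_setequal(unique(cmp$source), c("data", "surrogate"))
  expect_equal(nrow(cmp), 2 * (1 + 2))
  full_h <- cmp$h_x[cmp$variant == "full" & cmp$source == "data"]
  jump_h <- cmp$h_x[cmp$variant == "jump" & cmp$source == "data"]
  # removing duplicates increases apparent randomness
  expect_gt(jump_h, full_h)
  # jump sequences lose long-range structure
  jump_H <- cmp$H_mean[cmp$variant == "jump" & cmp$source == "data"]
  expect_equal(jump_H, 0.5, tolerance = 0.15)
  # surrogates of a first-order Markov source match its entropy rate
  surr_h <- cmp$h_x[cmp$variant == "full" & cmp$source == "surrogate"]
  expect_equal(mean(surr_h), full_h, tolerance = 0.02)
  # short jump sequences carry a bias warning
  expect_warning(
    compare_with_surrogates(s, n_surrogates = 1, seed = 28),
    "bias")
})

test_that("plot helpers return ggplot objects", {
  m <- diagonal_markov_model(4, 0.9)
  conv <- run_convergence(m, lengths = c(1000, 3000), n_replicates = 2,
                          seed = 29)
  expect_s3_class(plot_convergence(conv), "ggplot")
  sw <- run_temperature_sweep(L = 6, rel_temps = c(0.8, 1.6),
                              n_iterations = 600, warmup = 100, n_nodes = 2,
                              n_runs = 1, seed = 30, scale_min = 16,
                              scale_max = 150)
  expect_s3_class(plot_sweep(sw), "ggplot")
})
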