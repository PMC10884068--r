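#' Critical temperature of the 2D Q-state Potts model
#'
#' The standard ferromagnetic Potts model on the square lattice has the
#' exactly known critical temperature `T_c = 1 / log(1 + sqrt(Q))` in units of
#' the coupling constant (J = +1, Boltzmann constant 1). For Q = 4 the phase
#' transition is second order, for Q >= 5 first order.
#'
#' @param Q Integer number of states, at least 2.
#' @return The critical temperature (numeric scalar).
#' @examples
#' critical_temperature(4)  # 1/log(3) ~ 0.910
#' @export
critical_temperature <- function(Q) {
  if (length(Q) != 1L || is.na(Q) || Q < 2) abort("Q must be an integer >= 2")
  1 / log(1 + sqrt(Q))
}

#' Create a random Potts lattice
#'
#' Each site is initialised iid uniformly over the Q states (0-based codes),
#' the "random initial state" from which a simulation relaxes during warm-up.
#' Boundary conditions are periodic throughout the module, so every site has
#' exactly 4 nearest neighbours and bulk behaviour matches the analytic
#' critical temperature.
#'
#' @param L Linear lattice size (L x L sites), at least 2.
#' @param Q Number of states.
#' @return An integer L x L matrix of states in `[0, Q)`.
#' @export
potts_lattice <- function(L, Q) {
  if (L < 2) abort("L must be >= 2")
  if (Q < 2) abort("Q must be >= 2")
  matrix(sample.int(Q, L * L, replace = TRUE) - 1L, nrow = L)
}

#' Per-site Potts energy
#'
#' The energy of site (k, l) is minus the number of its 4 nearest neighbours
#' (periodic boundaries) in the same state, i.e. the ferromagnetic
#' nearest-neighbour Hamiltonian with J = +1 evaluated at one site. Note that
#' summing this quantity over all sites counts every bond twice; the total
#' lattice energy is half that sum.
#'
#' @param grid Integer L x L state matrix.
#' @param k,l 1-based row and column index of the site.
#' @return The site energy (0, -1, ..., -4).
#' @export
site_energy <- function(grid, k, l) {
  L <- nrow(grid)
  if (ncol(grid) != L) abort("grid must be square")
  if (k < 1 || k > L || l < 1 || l > L) abort("site index out of range")
  q <- grid[k, l]
  up    <- grid[if (k == 1) L else k - 1, l]
  down  <- grid[if (k == L) 1 else k + 1, l]
  left  <- grid[k, if (l == 1) L else l - 1]
  right <- grid[k, if (l == L) 1 else l + 1]
  -sum(c(up, down, left, right) == q)
}

#' Total lattice energy (single bond count)
#'
#' Sums `-delta(q_i, q_j)` over every nearest-neighbour bond once. Used as the
#' brute-force reference for the incremental energy bookkeeping of the
#' Metropolis sweep.
#'
#' @param grid Integer L x L state matrix.
#' @return Total energy (integer-valued numeric).
#' @export
lattice_energy <- function(grid) {
  right <- grid[, c(2:ncol(grid), 1)]
  down <- grid[c(2:nrow(grid), 1), ]
  -(sum(grid == right) + sum(grid == down))
}

#' One or more Metropolis sweeps of the Potts lattice
#'
#' A sweep performs L^2 single-site update attempts. Each attempt picks a
#' uniformly random site and proposes a uniformly random new state (self
#' proposals allowed and trivially accepted); the move is accepted with
#' probability `min(1, exp(-dE / T))`, where dE is the change in total lattice
#' energy from that site's 4 bonds. Energy-lowering moves are therefore always
#' accepted. Randomness comes from R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param grid Integer L x L state matrix (0-based states).
#' @param Q Number of states.
#' @param T Temperature, must be > 0 (units of J).
#' @param nsweeps Number of full sweeps to perform.
#' @param record_sites Optional two-column matrix of 1-based (row, col) site
#'   indices whose states are recorded after every sweep.
#' @return A list with `grid` (post-sweep lattice), `dE_total` (incrementally
#'   accumulated energy change, equal to the difference of [lattice_energy()]
#'   before and after), and `recorded` (sites x sweeps integer matrix, empty
#'   unless `record_sites` is given).
#' @export
metropolis_sweep <- function(grid, Q, T, nsweeps = 1L, record_sites = NULL) {
  if (T <= 0) abort("temperature must be > 0")
  if (any(grid < 0L) || any(grid >= Q)) abort("grid states must lie in [0, Q)")
  record <- !is.null(record_sites)
  if (record) {
    record_sites <- as.matrix(record_sites)
    rows <- as.integer(record_sites[, 1]) - 1L
    cols <- as.integer(record_sites[, 2]) - 1L
  } else {
    rows <- integer(0); cols <- integer(0)
  }
  # the C++ kernel updates a copy; R semantics are preserved
  potts_sweeps_cpp(grid + 0L, as.integer(Q), T, as.integer(nsweeps),
                   rows, cols, record)
}

#' Reference-protocol relative temperature grid
#'
#' The 17-point `T / T_c` grid used for the temperature-sweep experiments,
#' denser around the critical point.
#'
#' @return Numeric vector of relative temperatures.
#' @export
potts_temperature_grid <- function() {
  c(0.2, 0.4, 0.6, 0.8, 0.9, 1.0, 1.1, 1.2, 1.4,
    1.6, 1.8, 2.0, 2.2, 2.4, 2.6, 2.8, 3.0)
}

#' Simulate Potts node time courses across temperatures
#'
#' For every relative temperature and run: draw a fresh random lattice, run
#' `warmup` Metropolis sweeps to relax it, then record the state of `n_nodes`
#' randomly selected lattice sites after each of `n_iterations` further
#' sweeps. Each recorded node yields one [symbolic_sequence] of length
#' `n_iterations`. Runs are driven by per-run sub-seeds derived from `seed`,
#' so the full simulation is deterministic given `seed`, and the node subset
#' is resampled for every run.
#'
#' @param L Linear lattice size.
#' @param Q Number of Potts states.
#' @param rel_temps Relative temperatures `T / T_c` (see
#'   [potts_temperature_grid()] for the standard grid).
#' @param n_iterations Recorded sweeps per run.
#' @param warmup Discarded relaxation sweeps.
#' @param n_nodes Number of recorded lattice sites per run.
#' @param n_runs Independent repetitions per temperature.
#' @param seed Master RNG seed.
#' @return A tibble with one row per recorded node: columns `rel_temp`, `run`,
#'   `node`, `seed` and `seq` (list-column of `symbolic_sequence`). Sequence
#'   meta carries the same fields.
#' @examples
#' sims <- simulate_potts(L = 8, Q = 4, rel_temps = c(0.2, 3.0),
#'                        n_iterations = 200, warmup = 50,
#'                        n_nodes = 2, n_runs = 1, seed = 1)
#' sims
#' @export
simulate_potts <- function(L = 25, Q = 4, rel_temps = potts_temperature_grid(),
                           n_iterations = 30000, warmup = 2500,
                           n_nodes = 25, n_runs = 50, seed = 1) {
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (warmup < 0) abort("warmup must be >= 0")
  if (n_nodes < 1 || n_nodes > L * L) abort("n_nodes must lie in [1, L^2]")
  Tc <- critical_temperature(Q)
  grid_spec <- tidyr::expand_grid(rel_temp = rel_temps, run = seq_len(n_runs))
  set.seed(seed)
  grid_spec$sub_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid_spec))
  labels <- LETTERS[seq_len(Q)]
  rows <- purrr::pmap(grid_spec, function(rel_temp, run, sub_seed) {
    set.seed(sub_seed)
    lattice <- potts_lattice(L, Q)
    sites <- sample.int(L * L, n_nodes)
    site_mat <- cbind((sites - 1L) %% L + 1L, (sites - 1L) %/% L + 1L)
    T <- rel_temp * Tc
    if (warmup > 0) {
      lattice <- metropolis_sweep(lattice, Q, T, warmup)$grid
    }
    rec <- metropolis_sweep(lattice, Q, T, n_iterations,
                            record_sites = site_mat)$recorded
    tibble(
      rel_temp = rel_temp, run = run, node = seq_len(n_nodes),
      seed = sub_seed,
      seq = lapply(seq_len(n_nodes), function(i) {
        symbolic_sequence(rec[i, ], labels = labels,
                          meta = list(rel_temp = rel_temp, run = run,
                                      node = i, seed = sub_seed))
      })
    )
  })
  dplyr::bind_rows(rows)
}
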