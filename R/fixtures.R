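#' Generate synthetic microstate-like sequences
#'
#' Deterministic (seeded) generator for the sequence families used throughout
#' the package's tests and experiments:
#'
#' * `"iid_uniform"` - independent uniform draws over the alphabet; the
#'   maximum-entropy reference (h_X = log2(A) bits/sample, H = 0.5).
#' * `"markov_diagonal"` - first-order Markov chain with transition matrix
#'   `P = d * I + (1 - d) / (A - 1) * (1 - I)`. With the default `d = 0.9`
#'   this mimics empirical microstate sequences, whose transition matrices
#'   have their largest entries on the diagonal (states persist for several
#'   samples before switching).
#' * `"periodic"` - deterministic cycle through the first `period` states.
#' * `"constant"` - a single repeated state; zero entropy, LZ count 2.
#' * `"single_flip"` - a single persisting state change at `flip_pos` (state
#'   0 before, state 1 from there on); the walk embedding is a step function,
#'   which triggers the documented DFA pitfall of spuriously large Hurst
#'   exponents for near-constant sequences.
#' * `"potts_node"` - a single node time course from the Potts simulator at
#'   relative temperature `rel_temp` (delegates to [simulate_potts()]).
#'
#' @param kind One of the fixture kinds above.
#' @param A Alphabet size (default 4).
#' @param n Sequence length.
#' @param d Diagonal weight for `"markov_diagonal"` (default 0.9).
#' @param period Cycle length for `"periodic"` (default `A`).
#' @param flip_pos Position of the deviating sample for `"single_flip"`
#'   (default the middle).
#' @param rel_temp Relative temperature `T / T_c` for `"potts_node"`
#'   (default 1.0).
#' @param L Lattice size for `"potts_node"` (default 16).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `symbolic_sequence` with the generator settings recorded in
#'   `meta`.
#' @examples
#' generate_sequence("constant", n = 5)
#' s <- generate_sequence("markov_diagonal", A = 4, n = 1000, d = 0.9, seed = 1)
#' @export
generate_sequence <- function(kind = c("iid_uniform", "markov_diagonal",
                                       "periodic", "constant", "single_flip",
                                       "potts_node"),
                              A = 4, n = 30000, d = 0.9, period = A,
                              flip_pos = NULL, rel_temp = 1.0, L = 16,
                              seed = 1) {
  kind <- match.arg(kind)
  if (A < 2) abort("alphabet size A must be >= 2")
  if (n < 1) abort("sequence length n must be >= 1")
  labels <- LETTERS[seq_len(A)]
  meta <- list(kind = kind, seed = seed)
  states <- switch(kind,
    iid_uniform = {
      set.seed(seed)
      sample.int(A, n, replace = TRUE) - 1L
    },
    markov_diagonal = {
      if (d < 0 || d > 1) abort("diagonal weight d must lie in [0, 1]")
      meta$d <- d
      m <- diagonal_markov_model(A, d)
      return(add_meta(synthesize_surrogate(m, n, seed = seed), meta))
    },
    periodic = {
      if (period < 1 || period > A) abort("period must lie in [1, A]")
      meta$period <- period
      rep_len(seq_len(period) - 1L, n)
    },
    constant = rep(0L, n),
    single_flip = {
      flip_pos <- flip_pos %||% (n %/% 2)
      if (flip_pos < 1 || flip_pos > n) abort("flip_pos out of range")
      meta$flip_pos <- flip_pos
      x <- rep(0L, n)
      x[flip_pos:n] <- 1L
      x
    },
    potts_node = {
      meta$rel_temp <- rel_temp
      sims <- simulate_potts(L = L, Q = A, rel_temps = rel_temp,
                             n_iterations = n, warmup = 2500,
                             n_nodes = 1, n_runs = 1, seed = seed)
      return(add_meta(sims$seq[[1]], meta))
    }
  )
  symbolic_sequence(states, labels = labels, meta = meta)
}

#' Microstate-like diagonal Markov model
#'
#' The transition model behind `"markov_diagonal"` fixtures:
#' `P = d * I + (1 - d)/(A - 1) * (1 - I)` with uniform initial distribution.
#'
#' @param A Alphabet size.
#' @param d Diagonal (self-transition) probability.
#' @return A `transition_model`.
#' @export
diagonal_markov_model <- function(A, d = 0.9) {
  off <- (1 - d) / (A - 1)
  P <- matrix(off, A, A)
  diag(P) <- d
  transition_model(P, initial = rep(1 / A, A))
}

add_meta <- function(seq, meta) {
  seq$meta <- utils::modifyList(seq$meta, meta)
  seq
}
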