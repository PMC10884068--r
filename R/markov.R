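#' Estimate a first-order transition model from sequences
#'
#' Maximum-likelihood transition probabilities: `P[i, j]` is the number of
#' observed `i -> j` transitions divided by the number of transitions leaving
#' `i`. Counts from multiple sequences are pooled without bridging sequence
#' boundaries (no phantom transitions between the end of one sequence and the
#' start of the next). The initial distribution is the pooled empirical symbol
#' distribution, and the stationary distribution is computed as the left fixed
#' point of `P`. States never observed as a transition source receive a
#' uniform row and are flagged with a warning, which keeps surrogate synthesis
#' from deadlocking on rare states.
#'
#' @param seqs A `symbolic_sequence` or a list of them (all sharing one
#'   alphabet).
#' @return An object of class `transition_model`: a list with `P` (A x A
#'   row-stochastic matrix), `initial`, `stationary`, `A`, `labels` and
#'   `zero_rows` (codes of states with no outgoing counts). Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' m <- estimate_transition_matrix(
#'   symbolic_sequence(c("A", "A", "A", "B"), LETTERS[1:4]))
#' m$P["A", ]  # 2/3 A->A, 1/3 A->B
#' @export
estimate_transition_matrix <- function(seqs) {
  if (inherits(seqs, "symbolic_sequence")) seqs <- list(seqs)
  seqs <- lapply(seqs, as_symbolic_sequence)
  if (length(seqs) == 0L) abort("at least one sequence is required")
  labels <- seqs[[1]]$labels
  A <- length(labels)
  for (s in seqs) {
    if (!identical(s$labels, labels)) {
      abort("all sequences must share the same alphabet")
    }
    if (length(s$states) < 2L) abort("each sequence must have length >= 2")
  }
  counts <- matrix(0, A, A, dimnames = list(labels, labels))
  marg <- numeric(A)
  for (s in seqs) {
    x <- s$states
    n <- length(x)
    idx <- cbind(x[-n] + 1L, x[-1] + 1L)
    tab <- table(factor(idx[, 1], levels = 1:A), factor(idx[, 2], levels = 1:A))
    counts <- counts + as.matrix(tab)
    marg <- marg + tabulate(x + 1L, nbins = A)
  }
  out <- rowSums(counts)
  zero_rows <- which(out == 0) - 1L
  if (length(zero_rows)) {
    warn(sprintf("states with no outgoing transitions get a uniform row: %s",
                 paste(labels[zero_rows + 1L], collapse = ", ")))
  }
  P <- counts
  for (i in seq_len(A)) {
    P[i, ] <- if (out[i] > 0) counts[i, ] / out[i] else rep(1 / A, A)
  }
  initial <- marg / sum(marg)
  names(initial) <- labels
  stationary <- tryCatch(stationary_distribution(P), error = function(e) {
    rep(NA_real_, A)
  })
  names(stationary) <- labels
  structure(list(P = P, initial = initial, stationary = stationary,
                 A = A, labels = labels, zero_rows = zero_rows),
            class = "transition_model")
}

#' Construct a transition model from a matrix
#'
#' @param P Row-stochastic A x A matrix.
#' @param initial Initial distribution; defaults to the stationary
#'   distribution of `P`.
#' @param labels State labels; defaults to `LETTERS[1:A]`.
#' @return A `transition_model`.
#' @export
transition_model <- function(P, initial = NULL, labels = NULL) {
  P <- as.matrix(P)
  check_stochastic(P)
  A <- nrow(P)
  labels <- labels %||% LETTERS[seq_len(A)]
  stationary <- tryCatch(stationary_distribution(P),
                         error = function(e) rep(NA_real_, A))
  if (is.null(initial) && anyNA(stationary)) {
    abort("no unique stationary distribution; supply `initial` explicitly")
  }
  initial <- initial %||% stationary
  if (length(initial) != A || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    abort("initial must be a probability distribution over the A states")
  }
  dimnames(P) <- list(labels, labels)
  names(stationary) <- names(initial) <- labels
  structure(list(P = P, initial = initial, stationary = stationary,
                 A = A, labels = labels, zero_rows = integer(0)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> A = %d states\n", x$A))
  print(round(x$P, 4))
  cat("stationary:", paste(sprintf("%s=%.3f", x$labels, x$stationary),
                           collapse = " "), "\n")
  invisible(x)
}

#' @rdname estimate_transition_matrix
#' @param x A `transition_model`.
#' @param ... Unused.
#' @export
tidy.transition_model <- function(x, ...) {
  tibble(from = rep(x$labels, each = x$A),
         to = rep(x$labels, times = x$A),
         prob = as.vector(t(x$P)))
}

#' @rdname estimate_transition_matrix
#' @export
glance.transition_model <- function(x, ...) {
  tibble(A = x$A,
         entropy_rate = tryCatch(analytic_markov_entropy_rate(x),
                                 error = function(e) NA_real_),
         diag_mean = mean(diag(x$P)),
         n_zero_rows = length(x$zero_rows))
}

#' Synthesize a first-order Markov surrogate sequence
#'
#' Draws `X_1` from the model's initial distribution and each following state
#' from the transition row of its predecessor. Surrogates built from an
#' empirical [estimate_transition_matrix()] preserve a source sequence's
#' symbol distribution and lag-1 transition structure (hence its PAI
#' coefficients at lags 0 and 1) and nothing beyond, which makes them the
#' null model for testing higher-order structure.
#'
#' @param model A `transition_model` or row-stochastic matrix.
#' @param n Length of the surrogate (>= 1).
#' @param seed Optional integer seed; when given, the draw is wrapped in
#'   `set.seed(seed)` so the surrogate is fully reproducible, and recorded in
#'   the sequence meta.
#' @return A `symbolic_sequence` with `meta$surrogate = TRUE`.
#' @examples
#' m <- transition_model(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
#' synthesize_surrogate(m, 10, seed = 1)
#' @export
synthesize_surrogate <- function(model, n, seed = NULL) {
  if (!inherits(model, "transition_model")) model <- transition_model(model)
  if (n < 1) abort("surrogate length n must be >= 1")
  if (any(!is.finite(model$P))) abort("transition model contains non-finite rows")
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  cum_p <- t(apply(model$P, 1, cumsum))
  x <- markov_synth_cpp(cum_p, cumsum(model$initial), u)
  symbolic_sequence(x, labels = model$labels,
                    meta = list(surrogate = TRUE, seed = seed))
}

#' Shuffle surrogate (order-randomised control)
#'
#' Randomly permutes the sequence, destroying all temporal structure while
#' keeping the symbol distribution. A convenience null model for tests; the
#' substantive null model of the package is [synthesize_surrogate()].
#'
#' @param seq A `symbolic_sequence`.
#' @param seed Optional integer seed.
#' @return A shuffled `symbolic_sequence`.
#' @export
shuffle_surrogate <- function(seq, seed = NULL) {
  seq <- as_symbolic_sequence(seq)
  if (!is.null(seed)) set.seed(seed)
  symbolic_sequence(sample(seq$states), labels = seq$labels,
                    meta = list(surrogate = "shuffle", seed = seed))
}
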