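#' Plug-in block (joint) entropy
#'
#' Shannon entropy, in bits, of the empirical distribution of all overlapping
#' length-k windows ("words") of the sequence. This is the raw plug-in
#' (maximum-likelihood) estimator without bias correction: it converges to the
#' true block entropy from below as the sequence grows, a property the
#' entropy-rate convergence analysis relies on. Words are counted within a
#' single sequence only.
#'
#' @param seq A `symbolic_sequence` (or coercible).
#' @param k Block length, `1 <= k <= length(seq)`.
#' @return Entropy in bits (numeric scalar).
#' @examples
#' s <- symbolic_sequence(rep(c("A", "B"), 50))
#' block_entropy(s, 1)  # 1 bit
#' block_entropy(s, 2)  # 1 bit: only AB and BA occur, equiprobably
#' @export
block_entropy <- function(seq, k) {
  seq <- as_symbolic_sequence(seq)
  n <- length(seq$states)
  if (k < 1 || k > n) abort("block length k must satisfy 1 <= k <= length(seq)")
  counts <- block_counts(seq$states, n_states(seq), as.integer(k))
  entropy_bits(counts)
}

# frequency table of overlapping k-grams via base-A integer encoding
block_counts <- function(x, A, k) {
  n <- length(x)
  ids <- as.numeric(x[seq_len(n - k + 1L)])
  if (k > 1L) {
    for (j in 2:k) ids <- ids * A + x[j:(n - k + j)]
  }
  m <- A^k
  if (m <= 2^26) {
    tabulate(as.integer(ids) + 1L, nbins = m)
  } else {
    as.integer(table(ids))
  }
}

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Entropy rate and excess entropy from block-entropy scaling
#'
#' Computes the plug-in joint entropies `H(k)` for block lengths
#' `k = 1..k_max` and fits an unweighted ordinary least-squares line through
#' the points `(k, H(k))`. The slope estimates the entropy rate `h_X` in
#' bits/sample (the irreducible per-symbol randomness, a Kolmogorov-complexity
#' style measure); the y-axis intercept estimates the excess entropy `E` in
#' bits (the mutual information between past and future, a
#' statistical-complexity measure that peaks near phase transitions).
#'
#' The estimator needs `length(seq)` well above `A^k_max` words to be
#' unbiased; a warning is issued otherwise. Both quantities inherit the
#' from-below bias of the plug-in block entropies at finite sample size.
#'
#' @param seq A `symbolic_sequence` (or coercible).
#' @param k_max Largest block length in the fit (default 6).
#' @return An object of class `block_entropy_fit` with elements `h_x`
#'   (bits/sample), `excess_entropy` (bits), `k`, `H`, `fitted`, `residuals`,
#'   `n` (sequence length), `A` (alphabet size) and `k_max`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @examples
#' set.seed(1)
#' s <- symbolic_sequence(sample(0:3, 1e4, replace = TRUE),
#'                        labels = LETTERS[1:4])
#' glance(entropy_rate_excess(s))  # h_x close to 2 bits/sample
#' @export
entropy_rate_excess <- function(seq, k_max = 6) {
  seq <- as_symbolic_sequence(seq)
  if (k_max < 2) abort("k_max must be >= 2 (the linear fit needs two points)")
  n <- length(seq$states)
  if (k_max > n) abort("k_max exceeds the sequence length")
  A <- n_states(seq)
  if (n < A^k_max) {
    warn(sprintf(
      "sequence length %d is below A^k_max = %d words; block entropies will be strongly biased",
      n, A^k_max))
  }
  k <- seq_len(k_max)
  H <- vapply(k, function(kk) block_entropy(seq, kk), numeric(1))
  fit <- lm(H ~ k)
  structure(list(
    h_x = unname(coef(fit)[2]),
    excess_entropy = unname(coef(fit)[1]),
    k = k, H = H,
    fitted = unname(fitted(fit)),
    residuals = unname(residuals(fit)),
    n = n, A = A, k_max = k_max
  ), class = "block_entropy_fit")
}

#' @export
print.block_entropy_fit <- function(x, ...) {
  cat(sprintf(
    "<block_entropy_fit> k = 1..%d, n = %d, A = %d\n  entropy rate h_X = %.4f bits/sample\n  excess entropy E = %.4f bits\n",
    x$k_max, x$n, x$A, x$h_x, x$excess_entropy))
  invisible(x)
}

#' @rdname entropy_rate_excess
#' @param x A `block_entropy_fit`.
#' @param ... Unused.
#' @export
tidy.block_entropy_fit <- function(x, ...) {
  tibble(k = x$k, H = x$H, fitted = x$fitted, residual = x$residuals)
}

#' @rdname entropy_rate_excess
#' @export
glance.block_entropy_fit <- function(x, ...) {
  tibble(h_x = x$h_x, excess_entropy = x$excess_entropy,
         k_max = x$k_max, n = x$n, A = x$A,
         sigma = sqrt(mean(x$residuals^2)))
}

#' @rdname entropy_rate_excess
#' @param object A `block_entropy_fit`.
#' @export
autoplot.block_entropy_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$H)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linetype = 2) +
    ggplot2::labs(
      x = "block length k", y = "H(k) [bits]",
      title = sprintf("h_X = %.3f bits/sample, E = %.3f bits",
                      object$h_x, object$excess_entropy)) +
    ggplot2::theme_minimal()
}

#' Analytic entropy rate of a first-order Markov chain
#'
#' Returns `-sum_i pi_i sum_j P_ij log2 P_ij` in bits/sample, where `pi` is
#' the stationary distribution (left fixed point of the transition matrix).
#' `0 * log 0` is taken as 0. This is the exact value the plug-in and LZ-76
#' estimators converge to for surrogate sequences generated from the model.
#'
#' @param model A `transition_model` (see [estimate_transition_matrix()]) or a
#'   row-stochastic matrix.
#' @return Entropy rate in bits/sample.
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
#' analytic_markov_entropy_rate(P)  # binary entropy of 0.1: 0.4690 bits
#' @export
analytic_markov_entropy_rate <- function(model) {
  P <- if (inherits(model, "transition_model")) model$P else as.matrix(model)
  check_stochastic(P)
  rows <- apply(P, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  # deterministic chains have rate 0 under any weighting of the rows
  if (all(rows == 0)) return(0)
  pi <- stationary_distribution(P)
  sum(pi * rows)
}

check_stochastic <- function(P) {
  if (nrow(P) != ncol(P)) abort("transition matrix must be square")
  if (any(P < 0)) abort("transition probabilities must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    abort("rows of the transition matrix must sum to 1")
  }
  invisible(TRUE)
}

# left fixed point of P; errors when the eigenvalue 1 is not simple
stationary_distribution <- function(P) {
  ev <- eigen(t(P))
  near_one <- abs(ev$values - 1) < 1e-8
  if (sum(near_one) != 1L) {
    abort("transition matrix has no unique stationary distribution (reducible chain?)")
  }
  v <- Re(ev$vectors[, which(near_one)])
  v <- v / sum(v)
  if (any(v < -1e-10)) {
    abort("transition matrix has no unique stationary distribution")
  }
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Partial autoinformation profile
#'
#' The partial autoinformation (PAI) at lag k is the conditional mutual
#' information between a sample and its lag-k predecessor given all
#' intervening samples:
#' `pai(0) = H(X_t)`, `pai(1) = I(X_t; X_{t-1})`, and for k >= 2
#' `pai(k) = I(X_t; X_{t-k} | X_{t-1}, ..., X_{t-k+1})`.
#' It is the information-theoretic analogue of the partial autocorrelation
#' function: for a first-order Markov process all coefficients at lags >= 2
#' vanish, so the profile diagnoses how much sequence structure a first-order
#' surrogate can capture.
#'
#' Each coefficient is computed from the empirical joint distribution of
#' (k+1)-grams, with all marginals taken from that single joint table, so the
#' plug-in conditional mutual information is non-negative by construction.
#'
#' @param seq A `symbolic_sequence` (or coercible).
#' @param lag_max Largest lag (default 5). Reliable estimates need
#'   `length(seq)` well above `A^(lag_max + 1)`.
#' @return A tibble of class `pai_profile` with columns `lag` and `pai`
#'   (bits).
#' @examples
#' s <- symbolic_sequence(rep(c("A", "B"), 500))
#' pai(s, lag_max = 2)  # pai(0) = 1, pai(1) = 1, pai(2) = 0
#' @export
pai <- function(seq, lag_max = 5) {
  seq <- as_symbolic_sequence(seq)
  n <- length(seq$states)
  if (lag_max >= n) abort("lag_max must be smaller than the sequence length")
  if (lag_max < 0) abort("lag_max must be >= 0")
  A <- n_states(seq)
  vals <- vapply(0:lag_max, function(k) {
    if (k == 0) return(block_entropy(seq, 1L))
    counts <- block_counts(seq$states, A, k + 1L)
    arr <- array(counts, dim = rep(A, k + 1L))
    # dims: 1 = X_{t-k} (oldest), 2..k = intervening, k+1 = X_t
    h_joint <- entropy_bits(c(arr))
    if (k == 1) {
      entropy_bits(rowSums(arr)) + entropy_bits(colSums(arr)) - h_joint
    } else {
      mid <- 2:k
      h_past <- entropy_bits(c(apply(arr, c(1, mid), sum)))
      h_fut <- entropy_bits(c(apply(arr, c(mid, k + 1L), sum)))
      h_mid <- entropy_bits(c(apply(arr, mid, sum)))
      h_past + h_fut - h_mid - h_joint
    }
  }, numeric(1))
  out <- tibble(lag = 0:lag_max, pai = pmax(vals, 0))
  class(out) <- c("pai_profile", class(out))
  out
}

#' @rdname pai
#' @param object A `pai_profile`.
#' @param ... Unused.
#' @export
autoplot.pai_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$lag), y = .data$pai)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "lag [samples]", y = "partial autoinformation [bits]") +
    ggplot2::theme_minimal()
}
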