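#' Enumerate two-subset state partitions
#'
#' The DFA/Hurst analysis embeds a categorical sequence as a +1/-1 random
#' walk by splitting the alphabet into two subsets. All balanced-as-possible
#' unordered partitions are enumerated: a 4-state alphabet has exactly 3
#' (2,2)-partitions, a 5-state alphabet exactly 10 (2,3)-partitions, and a
#' binary alphabet the single trivial split. For even A, duplicates under
#' subset swap are removed by fixing the first state in the first subset.
#'
#' @param A Alphabet size (>= 2) or a `symbolic_sequence` whose alphabet is
#'   used.
#' @return A list of partitions, each a list with integer code vectors `plus`
#'   and `minus`.
#' @examples
#' length(enumerate_partitions(4))  # 3
#' length(enumerate_partitions(5))  # 10
#' @export
enumerate_partitions <- function(A) {
  if (inherits(A, "symbolic_sequence")) A <- n_states(A)
  if (A < 2) abort("alphabet size must be >= 2")
  k <- floor(A / 2)
  states <- 0:(A - 1)
  sets <- utils::combn(states, k, simplify = FALSE)
  if (A %% 2 == 0) {
    sets <- Filter(function(s) 0 %in% s, sets)
  }
  lapply(sets, function(s) list(plus = s, minus = setdiff(states, s)))
}

#' Detrended fluctuation analysis of a numeric series
#'
#' Classic DFA: the series is mean-subtracted and cumulatively summed into a
#' profile; for each window size s the profile is split into
#' `floor(n/s)` non-overlapping windows from the start (the trailing
#' remainder is discarded), each window is detrended by a least-squares
#' polynomial of order `detrend_order`, and `F(s)` is the root-mean-square
#' residual pooled over windows. The Hurst exponent is the unweighted OLS
#' slope of `log2 F(s)` versus `log2 s`. H = 0.5 indicates an uncorrelated
#' process, H > 0.5 long-range persistence.
#'
#' Windows whose residual variance is exactly zero give undefined logs; such
#' scales are excluded from the fit with a degeneracy warning, and a fully
#' constant input returns `H = NA`. Near-constant inputs (a handful of state
#' changes, as in the cold Potts model) produce step-like profiles and
#' spuriously large exponents, sometimes H > 1.5 - a known pitfall of the
#' method, reported rather than corrected.
#'
#' @param walk Numeric series, typically the +/-1 embedding from
#'   [apply_partition()].
#' @param n_scales Number of logarithmically spaced window sizes (default 50).
#' @param scale_min,scale_max Smallest and largest window size in samples
#'   (defaults 50 and 2500; duplicates after rounding are dropped).
#' @param detrend_order Polynomial detrending order (default 1, i.e. DFA1).
#' @return An object of class `dfa_fit` with `scales`, `F`, `H`, `n` and
#'   `degenerate` (flag). Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' set.seed(1)
#' fit <- dfa_fluctuation(sample(c(-1, 1), 10000, replace = TRUE),
#'                        scale_max = 1000)
#' fit$H  # ~ 0.5
#' @export
dfa_fluctuation <- function(walk, n_scales = 50, scale_min = 50,
                            scale_max = 2500, detrend_order = 1) {
  if (n_scales < 2) abort("n_scales must be >= 2")
  if (scale_min < 4) abort("scale_min must be >= 4")
  n <- length(walk)
  if (n < 2 * scale_max) {
    warn(sprintf("series length %d is below 2 * scale_max = %d; large scales are poorly sampled",
                 n, 2 * scale_max))
  }
  scales <- dfa_scales(n_scales, scale_min, scale_max)
  scales <- scales[scales <= n]
  profile <- cumsum(walk - mean(walk))
  F <- vapply(scales, function(s) fluctuation_at_scale(profile, s, detrend_order),
              numeric(1))
  ok <- is.finite(F) & F > 0
  degenerate <- any(!ok)
  if (degenerate) {
    warn("degenerate input: zero-fluctuation scales excluded from the Hurst fit")
  }
  H <- if (sum(ok) >= 2) {
    unname(coef(lm(log2(F[ok]) ~ log2(scales[ok])))[2])
  } else {
    NA_real_
  }
  structure(list(scales = scales, F = F, H = H, n = n,
                 detrend_order = detrend_order, degenerate = degenerate),
            class = "dfa_fit")
}

dfa_scales <- function(n_scales, scale_min, scale_max) {
  unique(round(exp(seq(log(scale_min), log(scale_max), length.out = n_scales))))
}

fluctuation_at_scale <- function(profile, s, order) {
  m <- length(profile) %/% s
  M <- matrix(profile[seq_len(s * m)], nrow = s)
  if (order == 1) {
    # closed-form linear detrending per window
    t <- seq_len(s)
    St <- sum(t); Stt <- sum(t^2)
    denom <- Stt - St^2 / s
    Sy <- colSums(M)
    Sty <- crossprod(t, M)[1, ]
    b <- (Sty - St * Sy / s) / denom
    ssr <- colSums(M^2) - Sy^2 / s - b^2 * denom
  } else {
    X <- stats::poly(seq_len(s), degree = order, raw = TRUE)
    X <- cbind(1, X)
    res <- stats::lm.fit(X, M)$residuals
    ssr <- colSums(as.matrix(res)^2)
  }
  sqrt(sum(pmax(ssr, 0)) / (s * m))
}

#' Hurst exponent of a categorical sequence via partition-embedded DFA
#'
#' Embeds the sequence as a +/-1 series for every two-subset partition of its
#' alphabet ([enumerate_partitions()]), runs [dfa_fluctuation()] on each
#' embedding, and averages the per-partition Hurst exponents. Averaging over
#' all partitions removes the arbitrariness of any single state split: a
#' 4-state sequence uses the 3 (2,2)-partitions, a 5-state one the 10
#' (2,3)-partitions.
#'
#' @param seq A `symbolic_sequence` (or coercible).
#' @inheritParams dfa_fluctuation
#' @return An object of class `hurst_fit`: a list with `H_mean`, a tibble
#'   `partitions` (partition label, per-partition H, degeneracy flag) and the
#'   list of per-partition `dfa_fit` objects (`fits`). Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @examples
#' set.seed(1)
#' s <- symbolic_sequence(sample(0:3, 20000, replace = TRUE), LETTERS[1:4])
#' glance(hurst(s, scale_max = 2000))$H_mean  # ~ 0.5
#' @export
hurst <- function(seq, n_scales = 50, scale_min = 50, scale_max = 2500,
                  detrend_order = 1) {
  seq <- as_symbolic_sequence(seq)
  parts <- enumerate_partitions(n_states(seq))
  fits <- lapply(parts, function(p) {
    dfa_fluctuation(apply_partition(seq, p$plus, p$minus),
                    n_scales = n_scales, scale_min = scale_min,
                    scale_max = scale_max, detrend_order = detrend_order)
  })
  lab <- vapply(parts, function(p) {
    paste0(paste(seq$labels[p$plus + 1L], collapse = ""), "|",
           paste(seq$labels[p$minus + 1L], collapse = ""))
  }, character(1))
  per_H <- vapply(fits, `[[`, numeric(1), "H")
  partitions <- tibble(partition = lab, H = per_H,
                       degenerate = vapply(fits, `[[`, logical(1), "degenerate"))
  # partitions whose walk is fully constant have undefined H; the average is
  # taken over the defined ones (degeneracy stays flagged per partition)
  structure(list(H_mean = mean(per_H, na.rm = TRUE), partitions = partitions,
                 fits = fits, n = length(seq$states)),
            class = "hurst_fit")
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("<dfa_fit> n = %d, %d scales in [%d, %d], H = %.3f%s\n",
              x$n, length(x$scales), min(x$scales), max(x$scales), x$H,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf("<hurst_fit> n = %d, %d partitions, mean H = %.3f\n",
              x$n, nrow(x$partitions), x$H_mean))
  print(x$partitions)
  invisible(x)
}

#' @rdname dfa_fluctuation
#' @param x A `dfa_fit`.
#' @param ... Unused.
#' @export
tidy.dfa_fit <- function(x, ...) {
  tibble(scale = x$scales, F = x$F)
}

#' @rdname dfa_fluctuation
#' @export
glance.dfa_fit <- function(x, ...) {
  tibble(H = x$H, n_scales = length(x$scales), n = x$n,
         degenerate = x$degenerate)
}

#' @rdname hurst
#' @param x A `hurst_fit`.
#' @param ... Unused.
#' @export
tidy.hurst_fit <- function(x, ...) x$partitions

#' @rdname hurst
#' @export
glance.hurst_fit <- function(x, ...) {
  tibble(H_mean = x$H_mean, n_partitions = nrow(x$partitions), n = x$n,
         degenerate = any(x$partitions$degenerate))
}

#' @rdname dfa_fluctuation
#' @param object A `dfa_fit`.
#' @export
autoplot.dfa_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[is.finite(d$F) & d$F > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scale, y = .data$F)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "scale s [samples]", y = "F(s)",
                  title = sprintf("H = %.3f", object$H)) +
    ggplot2::theme_minimal()
}

#' @rdname hurst
#' @param object A `hurst_fit`.
#' @export
autoplot.hurst_fit <- function(object, ...) {
  d <- purrr::map2_dfr(object$fits, object$partitions$partition,
                       function(f, p) mutate(tidy(f), partition = p))
  d <- d[is.finite(d$F) & d$F > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scale, y = .data$F,
                                  colour = .data$partition)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "scale s [samples]", y = "F(s)",
                  title = sprintf("mean H = %.3f", object$H_mean)) +
    ggplot2::theme_minimal()
}
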