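# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Brute-force LZ-76 parser, straight from the definition: each phrase is the
# shortest prefix of the remaining suffix that cannot be reproduced by copying
# from a start position strictly before the phrase (the copy may run
# self-referentially past its source). O(n^2)-ish; for short strings only.
lz76_oracle_count <- function(x) {
  n <- length(x)
  reproducible <- function(p, m) {
    # can x[p..p+m-1] (0-based p) be copied from some start i < p?
    for (i in seq_len(p) - 1L) {
      ok <- TRUE
      for (j in seq_len(m) - 1L) {
        if (x[i + j + 1L] != x[p + j + 1L]) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  c_n <- 0L
  p <- 0L
  while (p < n) {
    c_n <- c_n + 1L
    if (p == 0L) { p <- 1L; next }
    m <- 1L
    while (p + m <= n && reproducible(p, m)) m <- m + 1L
    if (p + m > n) m <- n - p  # final phrase reproducible to the end
    p <- p + m
  }
  c_n
}

# Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
# Serves as the spectral-synthesis oracle for DFA: a series with known Hurst
# exponent H generated by a route entirely independent of the DFA code.
fgn_oracle <- function(n, H) {
  gamma_k <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                                  abs(k - 1)^(2 * H))
  m <- 2 * n
  circ <- gamma_k(c(0:(n - 1), n, (n - 1):1))
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  w <- fft(sqrt(lambda / (2 * m)) * z)
  Re(w)[seq_len(n)]
}

# Per-symbol empirical frequencies of a symbolic sequence
state_freqs <- function(seq, A = length(seq$labels)) {
  tabulate(seq$states + 1L, nbins = A) / length(seq$states)
}

random_sequence <- function(n, A) {
  symbolic_sequence(sample.int(A, n, replace = TRUE) - 1L,
                    labels = LETTERS[seq_len(A)])
}
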