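# mscomplexity

Complexity metrics for categorical (microstate-like) time series in R.

EEG microstate analysis reduces a multichannel recording to a sequence of
labels over a small alphabet (typically 4–5 classes). How complex is such a
sequence? This package implements, for any symbolic sequence, the two
families of answers used in the microstate literature and the ground-truth
model needed to validate them:

* **Entropy rate and excess entropy** from block-entropy scaling: the joint
  entropies H(k) of overlapping length-k words (k = 1…6) are fit with a
  line; the slope is the entropy rate *h_X* (bits/sample, irreducible
  randomness — the Kolmogorov-complexity flavour) and the intercept the
  excess entropy *E* (bits, past–future mutual information — statistical
  complexity, peaking near phase transitions).
* **Lempel–Ziv (LZ-76) complexity**: the exhaustive-history phrase count
  c(n), rescaled as c(n)·log₂(n)/n to be directly comparable to *h_X*.
* **DFA Hurst exponents** of ±1 random-walk embeddings, averaged over all
  two-subset alphabet partitions (three (2,2)-partitions for 4 states, ten
  (2,3)-partitions for 5); H = 0.5 for uncorrelated sequences.
* **Partial autoinformation (PAI)** profiles and **first-order Markov
  surrogates**, to test how much sequence structure lives beyond the
  transition matrix.
* A **2D Q-state Potts model** Metropolis simulator with exactly known
  critical temperature T_c = 1/ln(1+√Q), used as a controllable ground
  truth: entropy rate rises sigmoidally through T_c, excess entropy and
  Hurst exponents peak there.
* **Jump sequences** (consecutive duplicates collapsed, ACCCAADBBA →
  ACADBA) and tidy experiment drivers for temperature sweeps, estimator
  convergence and data-vs-surrogate comparisons.

All drivers return tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

A microstate-like fixture: a 4-state first-order Markov chain with 0.9
self-transition probability, 30,000 samples (2 min at 250 Hz):

```r
library(mscomplexity)

s <- generate_sequence("markov_diagonal", A = 4, n = 30000, d = 0.9, seed = 7)
sequence_complexity(s)
#> # A tibble: 1 × 10
#>       n   h_x excess_entropy lzc_rate H_mean degenerate ...
#> 1 30000 0.637           1.37    0.657  0.598 FALSE      ...
```

The entropy rate (0.637 bits/sample) sits near the analytic value of the
generating chain, 0.627 bits/sample — well below the 2 bits/sample ceiling
of a memoryless uniform 4-state source, because the strong diagonal makes
the next state predictable. The LZ-76 rate (0.657) agrees with *h_X* from
above, as it must at finite length. The excess entropy (1.37 bits) measures
how much the past helps prediction; the Hurst exponent (0.598) sits close
to the uncorrelated value 0.5, as a memory-one process has no long-range
persistence at DFA scales.

The PAI profile shows the first-order signature — all structure is at lags
0 and 1:

```r
pai(s, lag_max = 3)
#> # A tibble: 4 × 2
#>     lag      pai
#> 1     0 2.00
#> 2     1 1.36
#> 3     2 0.000771
#> 4     3 0.00291
```

Ground truth from the Potts model, scaled down to run in minutes:

```r
sw <- run_temperature_sweep(L = 16, n_runs = 10, n_nodes = 10,
                            n_iterations = 10000, seed = 1)
plot_sweep(sw)   # h_X sigmoidal through T_c; E and H peak at T/T_c = 1
```

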