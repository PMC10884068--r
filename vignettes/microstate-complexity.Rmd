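---
title: "Complexity analysis of categorical time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity analysis of categorical time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscomplexity)
```

## Scope and the objects of study

`mscomplexity` quantifies the complexity of categorical time series over
small finite alphabets. The motivating application is EEG microstate
analysis, where a multichannel recording is reduced to a sequence of labels
over typically 4 or 5 classes, but nothing in the package is specific to
EEG: any symbolic sequence (here a `symbolic_sequence`, integer-coded with
display labels) is a valid input.

Two distinct notions of complexity are implemented side by side:

* **Algorithmic (Kolmogorov-style) complexity** — how random the sequence
  is once all regularities are accounted for. Estimated two ways: the
  entropy rate $h_X$ from block-entropy scaling, and the Lempel–Ziv (LZ-76)
  phrase count rescaled to bits/sample. For a stationary ergodic source both
  converge to the same limit.
* **Statistical complexity** — how much structure links past and future.
  Estimated as the excess entropy $E$ (the mutual information between the
  semi-infinite past and future), and, from a different theoretical
  framework, as long-range persistence via DFA Hurst exponents. These
  measures are small for both fully ordered and fully random sequences and
  peak in between, e.g. near a phase transition.

Because the ground truth of empirical brain data is unknown, the package
ships a ground-truth generator with a controllable phase transition: the
two-dimensional Q-state Potts model.

## The Potts simulator

The standard ferromagnetic Potts model places a state
$q \in \{0, \dots, Q-1\}$ on each node of an $L \times L$ square lattice.
A site's energy is $-J$ times the number of its four nearest neighbours in
the same state ($J = +1$). Sampling is Metropolis: a random site, a uniform
random proposed state, acceptance with probability
$\min(1, e^{-\Delta E / T})$. The model is simulated at temperatures
expressed relative to the exact critical temperature
$T_c = 1 / \ln(1 + \sqrt{Q})$.

Design choices the simulator makes where conventions vary:

* **Energy bookkeeping.** The per-site energy sums over that site's four
  bonds, so summing it over all sites counts every bond twice.
  $\Delta E$ for a single-site update uses the single-bond-count total
  ($\Delta E = -(n_\text{new} - n_\text{old})$ matching neighbours); this is
  the convention under which the analytic $T_c$ applies. With the
  double-count convention the whole temperature axis would be off by a
  factor of two.
* **Boundary conditions** are periodic, so every site has exactly four
  neighbours and bulk behaviour matches the analytic critical point.
* **One iteration = one full sweep** of $L^2$ single-site attempts, and one
  sample per recorded node per sweep. This is the conventional Monte-Carlo
  time unit and the only reading under which 30,000 recorded samples
  correspond to 30,000 iterations.
* **Proposals are uniform over all Q states**, self-proposals included
  (trivially accepted); the chain remains valid Metropolis.
* **Initial condition** is iid uniform ("random quench"), relaxed by a
  warm-up of discarded sweeps (default 2500). At deep sub-critical
  temperatures the quench freezes into multi-domain configurations whose
  walls never fully anneal; see *Limitations*.
* **Reproducibility.** A master seed draws per-run sub-seeds; each run
  re-draws its lattice, its recorded node subset (without replacement) and
  its dynamics from that sub-seed, so any subset of runs can be reproduced
  independently.

The reference protocol is $L = 25$, $Q = 4$, 50 runs, 25 recorded nodes,
30,000 recorded sweeps after 2500 warm-up sweeps, on a 17-point
$T/T_c$ grid from 0.2 to 3.0 densified around the critical point. The
package's scaled-down default for `run_temperature_sweep()`
($L = 16$, 10 runs, 10 nodes, 10,000 sweeps) preserves all qualitative
signatures and finishes in minutes on one core; the full protocol is a
parameter choice away.

## Entropy rate and excess entropy

For block length $k$, the block entropy $H(k)$ is the Shannon entropy (bits)
of the empirical distribution of all $n - k + 1$ overlapping length-$k$
words. For a stationary source $H(k) \approx E + h_X \, k$ for large $k$:
the entropy rate $h_X$ (bits/sample) is the asymptotic slope and the excess
entropy $E$ (bits) the intercept. `entropy_rate_excess()` fits an unweighted
OLS line through $(k, H(k))$ for $k = 1 \dots 6$ and reports slope and
intercept.

Choices and their rationale:

* **Raw plug-in estimator, no bias correction.** Maximum-likelihood word
  frequencies converge to the true block entropies from below; consequently
  $h_X$ is biased downwards at finite $n$. This behaviour is deliberate: the
  convergence experiment (`run_convergence()`) characterises exactly this
  from-below approach, mirrored by the LZ-76 estimator's from-above
  approach, and coverage-corrected estimators (Miller–Madow, NSB) would
  destroy that correspondence.
* **$k_{\max} = 6$, unweighted, $k = 1$ included.** The fit range is part
  of the estimator's definition here; weighting schemes are deliberately not
  offered. A warning is issued when $n < A^{k_\max}$, where the fit is
  dominated by undersampling bias.
* **Words are never pooled across sequences** — concatenation would
  manufacture phantom transitions at the joins.
* Base-2 logarithms throughout; units are bits and bits/sample.

For a first-order Markov chain the limit is known in closed form,
$h_X = -\sum_i \pi_i \sum_j P_{ij} \log_2 P_{ij}$
(`analytic_markov_entropy_rate()`), which anchors the convergence
experiments. Deterministic chains return 0 directly, since every row
contributes zero conditional entropy regardless of the stationary weights;
other chains without a unique stationary distribution are an error.

## LZ-76 complexity

`lz76_parse()` implements the 1976 exhaustive-history parsing: scanning left
to right, each new phrase is the shortest prefix of the remaining suffix
that cannot be reproduced by copying from a start position strictly inside
the already-seen text, with the copy allowed to run self-referentially into
the phrase being produced; the final phrase may be reproducible and counts
once. Correctness is defined by this rule — the test suite checks the
compiled implementation against a literal brute-force reproducibility
checker on a thousand random strings — while the implementation itself uses
candidate pruning (a candidate start is only extended if it matches at the
current best offset) to stay fast at $n = 10^5$.

The phrase count is rescaled as $c(n) \log_2(n) / n$ (`lz76_rate()`). This
is the normalisation under which the count of an iid uniform $Q$-state
sequence converges to $\log_2 Q$ bits/sample, making LZ-76 directly
comparable to $h_X$. Convergence is slow (order $1/\log n$) and from above,
so LZ values exceed block-entropy values at any practical length; the gap at
a given length is quantified by `run_convergence()`.

## DFA Hurst exponents

Categorical sequences have no natural magnitude, so the sequence is first
embedded as a $\pm 1$ series by splitting the alphabet into two subsets
(`apply_partition()`). All balanced two-subset partitions are used and the
resulting exponents averaged: three (2,2)-partitions for $A = 4$, ten
(2,3)-partitions for $A = 5$ (`enumerate_partitions()`).

`dfa_fluctuation()` is classic DFA1: cumulative sum of the mean-subtracted
series; for each of 50 log-spaced scales $s \in [50, 2500]$ samples
(deduplicated after integer rounding), the profile is cut into
$\lfloor n/s \rfloor$ non-overlapping windows from the start (the trailing
remainder is discarded — a single forward pass keeps the estimate simple
and strictly reproducible), each window is detrended by an order-1
least-squares polynomial, and $F(s)$ is the pooled RMS residual. $H$ is the
unweighted OLS slope of $\log_2 F$ vs $\log_2 s$. Linear detrending uses a
closed-form residual computation per window, so a full 50-scale analysis of
a 30,000-sample sequence costs milliseconds. $H = 0.5$ is the uncorrelated
reference; the scale range corresponds to 0.2–10 s at a 250 Hz sampling
rate, which is what lets DFA see structure invisible to the $k \le 6$
entropy window.

**Degenerate inputs.** A window with exactly zero residual variance makes
$\log F$ undefined. Zero-$F$ scales are excluded from the fit and the result
is flagged `degenerate`; a fully constant embedding returns `H = NA`. The
partition average is taken over the defined partitions. Near-constant
sequences — a handful of persisting state changes, typical of the frozen
Potts phase — produce step-like profiles and spuriously large exponents
(often $H > 1.5$); the package flags these rather than correcting them,
and downstream phenomenology summaries in the acceptance checks aggregate
Hurst exponents over non-degenerate estimates only, i.e. over the
estimator's validity domain.

## Partial autoinformation and Markov surrogates

Partial autoinformation (PAI) is the information-theoretic analogue of the
partial autocorrelation function: $\text{pai}(0) = H(X_t)$,
$\text{pai}(1) = I(X_t; X_{t-1})$, and for $k \ge 2$ the conditional mutual
information $I(X_t; X_{t-k} \mid X_{t-1}, \dots, X_{t-k+1})$. A first-order
Markov process has zero PAI at all lags $\ge 2$, so the profile shows
directly how much of a sequence's structure a first-order surrogate
captures. Each coefficient is computed from the empirical joint distribution
of $(k+1)$-grams with *all* marginals taken from that single table, which
makes the plug-in estimate non-negative by construction. (The alternative
telescoping form $2H_k - H_{k-1} - H_{k+1}$ over independently estimated
block entropies can go slightly negative through window-edge effects.)
Residual positive values at higher lags for genuinely Markov input are pure
estimator bias, growing with the conditioning-set size $A^{k-1}$; at
$A = 4$, $n = 30{,}000$ they stay below $10^{-2}$ bits through lag 5.

`estimate_transition_matrix()` pools transition counts across sequences
without bridging their boundaries; rows for states never observed as a
source fall back to uniform with a warning (this keeps synthesis from
deadlocking on rare states). `synthesize_surrogate()` starts from the
pooled empirical symbol distribution rather than the stationary
distribution, so that even short surrogates reproduce the source's marginal
(lag-0) statistics exactly in expectation — the property that makes
data-vs-surrogate PAI comparisons clean at lags 0 and 1.

## Jump sequences

`jump_sequence()` collapses consecutive duplicates (ACCCAADBBA → ACADBA),
the jump-chain representation from Markov process theory. Two consequences,
both reproduced by `compare_with_surrogates()`: apparent randomness rises
(the strong diagonal of microstate-like transition matrices is removed, so
entropy rate and LZC increase), and long-range correlations vanish (Hurst
exponents fall back to ≈0.5, since duration statistics carry the
long-memory information). Jump sequences are also several-fold shorter than
their sources; the comparison driver warns when a jump sequence falls below
$A^{k_\max}$ samples, where block-entropy estimates carry a substantial
small-sample bias.

## The synthetic-sequence generator

`generate_sequence()` provides the study conditions for every test and
experiment, without any external data:

| kind | emulates | default parameters |
|---|---|---|
| `iid_uniform` | maximum-entropy reference | $A=4$ |
| `markov_diagonal` | microstate-like persistence | $d = 0.9$, $A = 4$, $n = 30{,}000$ |
| `periodic`, `constant`, `single_flip` | metric edge cases | — |
| `potts_node` | criticality ground truth | $T/T_c = 1$, $L = 16$ |

The diagonal weight $d = 0.9$ reflects the empirical observation that
microstate transition matrices are diagonal-dominated (states persist for
tens of milliseconds at 250 Hz); $n = 30{,}000$ matches a 2-minute segment
at 250 Hz. What the generator does **not** emulate: non-Markovian duration
distributions, slow drifts and non-stationarity of real recordings,
unassigned/artefact samples, or any spatial (topographic) structure. Tests
passing on these fixtures therefore validate the estimators, not any claim
about real EEG.

## Problem sizes and numerical conventions

The test-suite experiments run at deliberately reduced scale, chosen so the
full suite completes in a few minutes while every qualitative signature
remains detectable: the sweep at $L = 16$, 10 runs × 10 nodes × 10,000
sweeps over the 17-point grid; convergence with 20 replicates on a 10-point
length grid in $[10^3, 10^5]$; estimator checks with 10–20 fixed seeds.
`run_convergence()` defaults to the reference 50 replicates.

Other conventions: state codes are 0-based internally (shared with the
Potts states and the C++ kernels), labels are display-only; all randomness
flows through R's RNG (`set.seed()` reproduces everything, including inside
the compiled kernels); OLS fits use `stats::lm`; stationary distributions
come from the left eigenvector of the transition matrix with the eigenvalue
1 required to be simple.

## Known limitations

* All entropy-family estimates are finite-sample biased (downwards for
  block entropies, upwards for LZ-76 rates); compare sequences of equal
  length, or consult `run_convergence()` for the expected bias at a given
  length.
* Excess entropy from a $k \le 6$ intercept is a lower-bound-flavoured
  proxy for the true past–future mutual information; no block-length
  extrapolation is attempted.
* DFA Hurst exponents are unreliable for sequences with very few state
  changes (flagged `degenerate`) — a property of the method, prominent in
  the frozen Potts phase but unlikely for well-sampled empirical microstate
  sequences of more than a few hundred samples.
* At deep sub-critical temperatures the simulator samples a quenched,
  slowly coarsening state, not the equilibrium ensemble; entropy rates
  there are dominated by rare domain-wall dynamics and differences between
  neighbouring cold grid points are below sampling resolution at reduced
  scale.
* Group statistics (ANOVA, post-hoc tests) are intentionally not wrapped:
  every experiment returns a tidy tibble ready for `aov()`,
  `TukeyHSD()` or mixed models.
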