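---
title: "Exact multiple-changepoint detection with pruned dynamic programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact multiple-changepoint detection with pruned dynamic programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpseg)
```

## The segmentation model

An ordered signal $y = (y_1, \dots, y_n)$ — a DNA copy-number profile along
a chromosome, a time series of rates — is modelled as piecewise constant:
changepoints $\tau_1 < \dots < \tau_k$ split it into $k + 1$ segments, the
$j$-th segment covering $y_{\tau_{j-1}+1}, \dots, y_{\tau_j}$ (with
$\tau_0 = 0$, $\tau_{k+1} = n$). Each segment is scored by a cost
$\mathcal{C}(\cdot)$, the minimised negative log-likelihood of a
single-parameter model for the data it contains:

* **Gaussian change in mean** (known noise s.d. $\sigma$):
  $\mathcal{C}(y_{s+1:t}) = \frac{1}{2\sigma^2}\sum_{i=s+1}^t (y_i - \bar
  y_{s+1:t})^2$, a scaled within-segment sum of squares. A length-linear
  constant has been dropped; it shifts every segmentation's cost equally and
  cannot change the optimum.
* **Poisson change in rate** (counts): pointwise loss $\mu - y\log\mu$ on
  $\mu \in (0, \infty)$; the segment cost is $S - S\log(S/m)$ for segment
  sum $S$ and length $m$, with an all-zero segment costing 0 (the
  $\mu \to 0^+$ limit).

Two exact formulations of "find the best segmentation" are supported.

**Penalised:** minimise total cost plus $\beta$ per changepoint,

$$F(n) \;=\; \min_{k,\tau} \sum_{j=0}^{k}
  \left[\mathcal{C}(y_{\tau_j+1:\tau_{j+1}}) + \beta\right] - \beta .$$

**Constrained:** for every $k \le K$, minimise total cost over
segmentations with exactly $k$ changepoints, $C_{k,n}$. The two meet
through the identity $\min_k [C_{k,n} + \beta k] = F(n)$ for any linear
penalty, which the test suite exercises directly.

## The six solvers

All six return the *global* optimum of their problem; they differ only in
how much of the search space they can discard.

| problem | unpruned | inequality pruning | functional pruning |
|---|---|---|---|
| penalised | `optimal_partitioning()` | `pelt()` | `fpop()` |
| constrained | `segment_neighbourhood()` | `snip()` | `pdpa()` |

The unpruned recursions are
$F(t) = \min_{0 \le \tau < t} [F(\tau) + \mathcal{C}(y_{\tau+1:t}) + \beta]$
with $F(0) = -\beta$, and
$C_{k,t} = \min_{k \le \tau \le t-1} [C_{k-1,\tau} +
\mathcal{C}(y_{\tau+1:t})]$, each $O(n^2)$ per penalty or per $k$.

**Inequality pruning** discards a candidate last changepoint $s$ forever
once $F(s) + \mathcal{C}(y_{s+1:t}) + \kappa > F(t)$ (penalised) or
$C_{k-1,s} + \mathcal{C}(y_{s+1:t}) + \kappa > C_{k-1,t}$ (constrained).
It needs only the subadditivity condition C2:
$\mathcal{C}(y_{s+1:t}) + \mathcal{C}(y_{t+1:T}) + \kappa \le
\mathcal{C}(y_{s+1:T})$ for all $s<t<T$. Both built-in families satisfy it
with $\kappa = 0$, which is the default everywhere.

**Functional pruning** needs the stronger condition C1 — the segment cost
is the minimum over a shared scalar parameter $\mu$ of summed pointwise
losses. Each candidate $\tau$ then carries its cost *as a function of*
$\mu$: for the Gaussian loss a quadratic $a\mu^2 + b\mu + c$ updated in
O(1) per observation, for the Poisson loss $m\mu - s\log\mu + o$. The
pointwise minimum of these curves partitions the $\mu$ axis into intervals,
one per currently-optimal candidate; a candidate whose interval set becomes
empty can never be optimal again and is dropped. The new candidate at time
$t$ enters on the complement of the union of the level sets
$\{\mu : \mathrm{Cost}^\tau_t(\mu) \le F(t) + \beta\}$ (constrained analogue:
threshold $C_{k-1,t}$).

Functional pruning provably discards every candidate that inequality
pruning does, at the same time step, in both problem classes. The package
checks this *set inclusion* (not just counts) in its tests, and
`candidate_count_experiment()` reproduces the averaged candidate-count
curves: on the standard 100-point design the mean FPOP candidate set stays
bounded (around 3–4) while PELT's grows roughly linearly between changes
(peaking around 20).

## Parameters that matter

* `beta` — the penalty per changepoint, in units of the (standardised)
  cost. `penalty_value(n)` gives the default $2\log n$, a choice that
  behaves well across simulation scenarios when the signal has first been
  MAD-standardised; $\log n$ is more permissive, $3\log n$ more
  conservative. Larger `beta` never yields more changepoints (tested).
* `K` — the largest number of changes solved for in the constrained
  problem. Cost $C_{k,n}$ is non-increasing in $k$, so `K` should exceed
  any plausible change count; `select_k()` then minimises
  $C_{k,n} + f(k,n)$.
* `sigma` — the Gaussian noise s.d. Internally the solvers work on
  `values / sigma` with unit variance, so the recommended workflow is
  `mad_standardise()` first and `sigma = 1` (the default). The estimator is
  $\hat\sigma = \mathrm{median}(|y_{i+1} - y_i|)/(\sqrt{2}\,z_{0.75})$:
  first differences cancel the piecewise-constant mean except at the few
  changepoints, which the median ignores. (The acronym MAD is used here,
  as in the changepoint literature, for the *median* absolute deviation of
  first differences scaled for normal consistency.)
* `kappa` — the C2 constant for the inequality rules. Both families are
  C1, hence C2 with $\kappa = 0$; the argument exists for cost families a
  user might add where C2 holds with $\kappa \ne 0$ only.

## Numerical and design choices

* **Tie-breaking.** All argmins over $\tau$ resolve to the smallest
  $\tau$; the brute-force oracles resolve exact ties toward the
  lexicographically smallest changepoint set. Ties have probability zero
  for continuous data and any convention attains the same optimum.
* **Interval sets** are closed, with $\pm\infty$ sentinels; boundary
  points shared by two candidates are measure-zero ties and are assigned to
  the older (smaller-$\tau$) candidate. The Gaussian parameter domain is
  the whole real line, so the freshly added candidate — which owns the two
  unbounded tails — always survives its first step.
* **Level-set roots.** Gaussian level sets come from the quadratic
  formula; a negative discriminant, however tiny, is an empty set (no
  zero-width survivors from floating noise). Poisson level sets have no
  closed form; each side of the convex curve is bracketed and bisected to
  relative tolerance $10^{-10}$.
* **Pruning-rule boundary cases.** The penalised inequality rule keeps
  candidates on $\le$; the constrained rule uses strict $<$, so a candidate
  exactly tied with the bound is dropped there. A dropped tied candidate
  can never be strictly better than the always-admitted candidate $t$, so
  both conventions attain the optimum; only which of several equal-cost
  segmentations is reported could differ, and only on exact-tie inputs.
* **Degenerate inputs.** A constant series has zero cost as one segment,
  so no changes are reported at any positive penalty; an all-zero Poisson
  segment costs 0 by the $\mu \to 0^+$ limit; the minimum segment length is
  one observation ($\tau = t - 1$ is always admissible), which the
  exactness proofs require — no option to force longer segments is offered.
* **Seeding.** `generate_signal()` seeds R's Mersenne Twister from the
  spec and restores the caller's RNG state; replicate $r$ of an averaged
  experiment uses `seed + r`, making every curve re-runnable.

## What the simulator does and does not emulate

`signal_spec()` defaults encode the reference design used in the pruning
diagnostics: $n = 100$, changes at $t = 20, 40, 60, 80$. The caption that
design comes from fixes the changepoint locations but not the segment
means or noise, so the generator exposes both as parameters; the defaults
chosen here — means alternating 0 and 5 with $\sigma = 1$, i.e. $5\sigma$
shifts — are this package's own choice of a strong, unambiguous signal.
The simulator draws independent Gaussian noise around an exactly
piecewise-constant mean. Real copy-number profiles deviate from this in
ways the simulator deliberately ignores: heavy-tailed outliers, wavy
GC-content trends, autocorrelated noise, and probe-specific variance.
Passing tests therefore certify the *optimisation* claims (the solvers
find the exact optimum of their stated criterion, and prune as claimed) —
not that the Gaussian criterion itself is the right model for any
particular data set. MAD standardisation recovers some robustness to
scale, none to autocorrelation.

## Problem sizes used in the checks

The package's own verification uses exhaustive enumeration ($2^{n-1}$
segmentations) up to $n = 10$–12, cross-solver exactness on 20 simulated
profiles of $n = 10^4$ with changes every 200 points ($K = 10$), the
candidate-count experiment at 1000 replicates of the 100-point design,
and 500-replicate recovery runs. These sizes make the whole suite run in
a couple of minutes on one core while still covering the $O(n^2)$ and
pruned regimes; all of them are set in the scripts and can be raised.

## Known limitations

* Scalar segment parameters only: functional pruning tracks interval sets
  on a one-dimensional $\mu$ axis. Multivariate losses would need
  higher-dimensional optimality regions, which is out of scope (SNIP-style
  inequality pruning is the usual recourse there).
* Costs with non-linear per-segment length terms (e.g. MDL's
  $\log(t-s)$) satisfy only C2; they would restrict the toolkit to the
  inequality-pruned and unpruned solvers and are not implemented.
* Approximate methods (binary segmentation and relatives) are outside the
  package's scope on purpose: every solver here is exact, so any two of
  them disagreeing on the same input is a bug, and the test suite treats
  it as such.
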