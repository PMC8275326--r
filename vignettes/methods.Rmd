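---
title: "Methods: deterministic batch Bayesian optimization over partition trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic batch Bayesian optimization over partition trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontierBO)
```

## The model and its assumptions

`frontierBO` maximizes an expensive black-box objective `f` over a search
space scaled to the unit hypercube. The statistical model is a
Gaussian process with zero prior mean and a Matérn ν = 5/2 kernel of
amplitude σ² and length scale ℓ, conditioned on the evaluations made so
far; replayed laboratory measurements are treated as noiseless up to a
fixed jitter σ²ₙ on the kernel diagonal. The posterior at a query point is
the standard closed form

μ(x) = k(x, X)(K + σ²ₙI)⁻¹y,  v(x) = k(x, x) − k(x, X)(K + σ²ₙI)⁻¹k(X, x),

computed through a cached Cholesky factorization (`gp_posterior()` agrees
with a dense `solve()` oracle to 1e-8 in the tests).

The search itself is *bound-based* rather than acquisition-maximizing: a
hierarchical partition tree is grown over the hypercube by trisecting
selected boxes along their longest side, and decisions compare ground-truth
values of evaluated box centers with upper confidence bounds
UCB(x) = μ(x) + B·√v(x) at unevaluated ones. The assumptions this encodes:

* `f` is bounded and continuous enough that a box's center value is
  informative about the box at the scale of its diameter;
* evaluations are expensive but the GP algebra is not (budgets of tens of
  evaluations, kernel matrices well under 10³);
* the lab can run up to `k` experiments at once, so batches of up to `k`
  requests per round are free parallelism.

## The iteration

One iteration makes a full three-step pass (see `fbo_optimize()`):

1. **Identify.** Depths are walked top-down; at each depth the leaf with
   the best associated value is examined. The running incumbent starts at
   the root's ground truth and is updated *only* when a candidate is
   selected. A ground-truth leaf at or above the running incumbent becomes
   a division candidate; below it, the depth is skipped; an unevaluated
   (UCB-valued) best leaf triggers a frontier computation, a batch request
   of up to `k` experiments, and a re-examination of the depth.

   The exact bookkeeping of the running incumbent matters more than it
   looks: an early version of this package also folded the values of
   already-divided boxes at every depth into the running incumbent. That
   variant suppresses division candidates (one division per pass), never
   accumulates unevaluated leaves, and was caught because the conventional
   GP baselines outperformed the deterministic search on the multimodal
   test fixture — inverting the relationship the acceptance study checks.
   With the rule as specified, the worked 1-D example reproduces the
   reference dynamics (11 iterations for a 50-evaluation budget).

2. **Prune.** For each candidate at depth `p`, a *virtual* trisection tree
   is grown from its box (default 4 levels; nothing is evaluated) and the
   UCB at every virtual center is computed. The candidate is kept iff some
   virtual UCB exceeds the value of at least one real node deeper than
   `p` — i.e. unless every deeper part of the tree already dominates
   anything the model hopes to find inside the box. With no deeper nodes,
   or with look-ahead 0, the candidate is kept vacuously.

3. **Divide and select.** Survivors are trisected. The middle child
   inherits the parent's ground truth (same center); each outer child's
   UCB is compared with the incumbent ν_max: below it, the UCB simply
   becomes the child's cached value; at or above it, the child is a
   *mandatory* evaluation. The batch is then filled to `k` from the
   frontier.

After the batch is ingested the GP hyperparameters are refit and every
cached leaf UCB is recomputed (the model changed).

## The frontier

Unevaluated leaves are encoded as points (tree depth, UCB); depth is
inversely proportional to box size, so the scatter spans the
exploration–exploitation trade-off. The batch candidates are the points on
the *upper convex hull* of this scatter, after removing points dominated at
their own depth (another point at the same depth with strictly greater
UCB). Collinear hull points are included — the paper's permissive reading;
inclusion can only add batch candidates and never excludes a hull vertex.
The hull is computed over raw integer depth by a monotone-chain scan and is
verified in the tests against a brute-force chord oracle on all random
point sets of up to 8 points (1,000 seeded trials).

Two design choices here were genuinely open:

* **Potential-optimality filter.** Only leaves with UCB ≥ ν_max enter the
  hull computation. The module contract for the pure hull says nothing
  about ν_max, but the step-3 semantics ("all new centers below the
  incumbent and an empty frontier give an empty batch") force the filter
  at the optimizer level, and it matches the stated intent that the hull
  avoids requesting experiments the model believes suboptimal.
* **Mandatory overflow.** Mandatory nodes always enter the batch even when
  they exceed `k`; the dispatcher splits oversized batches into FIFO
  chunks of `k`. The serial-inclusion guarantee (below) takes precedence
  over the cap.

**Serial inclusion.** The batch is the head of a deterministically ordered
queue (mandatory first, then frontier by UCB descending, ties by depth then
lexicographic center), so the single request a `k = 1` run of the same
state would make is always the first element. Every run records, at each
batch construction, the `k = 1` pick alongside the issued batch
(`result$serial_log`), and the acceptance tests assert containment at every
iteration.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `k` | 4 | parallelism level; the replayed sweep study's setting (3 in the live-lab workflow) |
| `budget` | 25 | total ground-truth evaluations; UCB placeholders are free |
| `sigma`, `lengthscale` | 1, 0.25 | initial kernel amplitude and length scale on the unit hypercube |
| `noise` | 1e-6 | jitter; replayed data are noiseless, raise for noisy labs |
| `eta` | 0.05 | UCB confidence parameter in B(M, η) = √(2 ln(π²M²/12η)); the coefficient convention of the serial bound-based method this extends — the exact constant is not canonical, any non-decreasing B preserves the structure |
| `lookahead` | 4 | virtual-tree depth in step 2 |
| `refit_restarts`, `refit_seed` | 5, 0 | multi-restart L-BFGS-B over (σ, ℓ) ∈ [1e-3, 10]², log-scale, fixed internal seed so refits are deterministic and idempotent |

The UCB counter M advances once per queried *point*, including step-2
virtual centers. B depends on M only through ln M, so the counting
granularity is immaterial in practice (B stays within roughly 2.4–5.2 over
a typical run); it is recorded here because the spec of the coefficient
left it open.

## Finite candidate sets

Replayed instrument sweeps offer a finite table of configurations. An
interval center is assigned the nearest *unused* candidate by Euclidean
distance in scaled space (never native units); equidistant ties break by
row order; each configuration is evaluated at most once per run. When the
set is exhausted a node simply keeps its UCB and the loop stops with a
message — in all intended uses the budget is far below the table size.
Categorical settings are embedded as equally spaced ordered levels in the
order listed (first level 0, last 1); whether a one-hot embedding would
serve better is unknown, but the ordered embedding is what the replayed
workflow used and keeps distances meaningful.

## Objectives

Raw endpoints are min–max scaled per column so differently distributed
endpoints combine on a common scale; in replayed mode the scaling uses the
full table (reproducing per-dataset objective values), while in live mode
it would have to be a running rescaling — a different regime, so the
package only implements the replayed scope and documents the difference.
Directions: height and SNR are maximized by default, width minimized
(exposed as negated scaled width). The SNR direction is genuinely
ambiguous in the source material (a "small SNR" is called good in prose,
yet SNR is *added* in the combined objective); both directions are exposed
via `snr_direction`, defaulting to maximize so that `Combo2 = SNR + Combo1`
reads literally.

Numerical guards: `combo1()` clamps the scaled width at ε = 1e-3 before
inversion, because min–max scaling sends the narrowest peak's width to
exactly 0 and the formula as printed is singular there; clamping preserves
the ranking. A constant endpoint column scales degenerately to 0.5 with a
warning. The resolution constant defaults to c = 1.18, the standard
Gaussian half-height factor; the source names c but gives no value.

## Synthetic fixtures: what they emulate and what they do not

`generate_sweep()` emulates a 4-parameter, 120-configuration full-factorial
instrument sweep: a seeded response surface on the scaled grid (a single
Gaussian bump; plus two decoy bumps for the multimodal family; plus small
observation noise for the rugged family) from which height, width and SNR
columns are derived with a tiny tie-breaking jitter, a planted optimum row,
and a machine-readable answer key. `generate_chromatogram()` emulates a
peak list (elution time, half-height width) whose resolution is known in
closed form.

What a green test on these fixtures establishes: that the optimizer's
*mechanics* — division, frontier batching, one-use assignment, budget
accounting — recover a planted optimum on smooth and moderately deceptive
surfaces with the benchmark's budget, and that it weakly dominates the
mean success rate of every conventional baseline run under the same
protocol. What it does not establish: performance on real spectra (real
endpoint surfaces are anisotropic, heteroscedastic and potentially much
rougher), robustness to replicate noise, or live-lab queue behaviour. The
rugged family is deliberately present as a harder world and is *not* part
of the acceptance claims.

## The simulated lab and asynchrony

`lab_queue(k, latency)` is a discrete-event virtual-time queue: at most `k`
jobs run at once, jobs start FIFO as slots free, and per-job durations come
from a constant or seeded log-normal latency model. The default optimizer
contract is a per-iteration barrier (dispatch the batch, wait for all).
With `async = TRUE` results are ingested in virtual completion order with
a surrogate refit per arrival, but batch boundaries still gate the next
identification pass — mandatory results must be in — which is what
preserves the serial-inclusion guarantee while still modelling queue-time
savings. Makespans obey `makespan(k = 1) = Σ durations` and are
non-increasing in `k` (`elapsed_virtual_time()`).

## Determinism and reproducibility

The optimizer has no randomness: request sequences are byte-identical
across runs. All tie-breaks are fixed (lowest-index dimension for equal
sides, lexicographic centers for equal values, row order for equidistant
candidates). The only internal stochastic component — refit restarts —
runs under a fixed private seed that saves and restores the global RNG
state, so user seeds are never perturbed. Baselines and fixture
generators take explicit seeds and are reproducible under them.

## Known limitations

* No replicate-aware noise modelling; the jitter is a single fixed scalar.
* Historical data condition the surrogate but never pre-grow the tree: the
  search always starts at the center of the space, however much prior data
  exist.
* No fully Bayesian treatment of the kernel hyperparameters (point
  estimates by marginal likelihood only), and no kernels beyond
  Matérn 5/2 and the squared exponential.
* The live-mode running-rescaling regime for objectives is documented but
  not implemented; replayed-mode scaling is the supported scope.
* The regret guarantees of the underlying serial method are inherited
  structurally (serial inclusion), not re-proved; tests check qualitative
  regret monotonicity only, since the constants in the exponential rate
  are not implementable as a test.
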