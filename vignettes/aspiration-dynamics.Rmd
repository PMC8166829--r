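---
title: "Aspiration dynamics on weighted networks: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aspiration dynamics on weighted networks: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspiradyn)
```

## The model and its assumptions

A population of `N ≥ 2` individuals sits on a fixed undirected weighted
graph; `w_ij ≥ 0` is the interaction rate between `i` and `j`, with no
self-loops and no isolated vertices (`d_i = Σ_j w_ij > 0`). Each individual
plays one of two strategies in a symmetric 2×2 game with payoffs
`(a, b, c, d)` and receives the edge-weighted *average* payoff
`π_l(s) = Σ_k (w_lk/d_l)·payoff(s_l, s_k)`; an accumulated mode
(`d_l · π_l`) is available everywhere through `payoff_mode`.

Updating is self-evaluation based: per time step one individual `l` is
drawn uniformly, computes its dissatisfaction `α_l − π_l(s)` against a fixed
aspiration `α_l`, and abandons its strategy with probability
`g_l(β(α_l − π_l))`. The update functions must be probabilities, strictly
increasing, and positive at zero; any number of distinct `g_l` may coexist
in one population. Aspirations are either *personalized* (fixed per
individual, strategy-independent) or *strategy-contingent* (`α_A`, `α_B`);
in the contingent mode an individual evaluates the aspiration of the
strategy it currently uses. There is no aspiration learning — levels are
constants of the run.

These choices give an irreducible, aperiodic Markov chain on the
`M = 2^N` strategy words (indexed by decimal value plus one, individual 1
on the least-significant bit), with off-diagonal transitions only between
states at Hamming distance one.

## The weak-selection machinery

At `β = 0` switching probabilities are payoff-independent, the chain is
doubly stochastic, and the stationary distribution is exactly uniform,
`u_0 = 2^(-N) 1`; both strategies then have abundance 1/2 and strategies of
distinct individuals are uncorrelated (`⟨s_l s_k⟩_0 = (1 + δ_lk)/4`). The
first-order expansion of the stationary abundance difference in `β` shows
that strategy A prevails iff `u_0ᵀ P_0' c > 0`, with `P_0'` the analytic
β-derivative of the transition matrix and `c` the accumulated
abundance-difference vector. Because individuals update independently at
neutrality, `c` factorizes over `N` two-state chains and has the closed
form `c_i = Σ_l (2 s_i(l) − 1)/(2 g_l(0))`.

`weak_selection_margin()` computes the margin through two genuinely
different code paths — the sparse-matrix contraction `u_0ᵀ P_0' c`, and the
state-enumerated average of the per-state satisfaction statistic
`h(s) = (1/N) Σ_l (g_l'(0)/g_l(0)) [(1 − 2 s_l) α_l(s) + (2 s_l − 1) π_l(s)]`
— and refuses to return if they disagree beyond 1e−9 relative. (Note the
sign of the payoff term: it must oppose the aspiration term, otherwise the
average over the neutral distribution would contradict the closed-form
result `(1/(4N)) (Σ_l g_l'(0)/g_l(0)) (a + b − c − d)`; the package's
consistency check enforces exactly this.) A companion brute-force oracle,
`c_vector_oracle()`, recomputes `c` by solving the resolvent system
`(I − P_0 + 1 u_0ᵀ) c = 2x − 1` with no use of the factorization; the test
suite holds the two equal exhaustively on all connected graphs up to four
vertices and on all 112 six-vertex graphs. Convergence of the underlying
series is taken as given once the neutral-balance precondition
`u_0ᵀ(2x − 1) = 0` holds; the oracle refuses to run without it.

For personalized aspirations the margin reduces to risk dominance
`a + b > c + d` with structure coefficient `σ = 1`; strategy-contingent
aspirations shift the threshold by `−2(α_B − α_A)`. `structure_coefficient()`
extracts `σ` non-symbolically from any margin evaluator by probing the four
basis games, verifying antisymmetry (`λ_a = −λ_d`, `λ_b = −λ_c`) and
linearity on a fifth probe, and returning `λ_a/λ_b`; it reports `σ` as
undefined rather than returning a ratio from a degenerate or non-linear
margin.

## Tunable parameters

* `beta` (selection intensity, dimensionless): 0 is neutral drift; the
  closed-form conditions are first-order in `beta`. Finite-β machinery
  defaults to `beta = 0.01`, small enough that exact-chain crossings sit
  within a few hundredths of the weak-selection threshold, large enough to
  resolve the crossing numerically.
* `alpha` (aspiration, payoff units): defaults in examples to 2.0 with the
  game `b = 0, c = 5, d = 1`, i.e. inside the payoff range; tests draw
  `α_l ∈ [0, 5]` to exercise the claim that the distribution is irrelevant.
* Update functions: the six built-ins (`g1` logistic, `g2` error-function,
  `g3` tanh, `g4` half-slope logistic, `g5`, `g6` asymmetric logistic
  variants) carry exact `g(0)` and `g'(0)`; user-supplied functions get a
  central finite difference (step 1e−6). The closed forms need
  `g'(0)/g(0)` exactly, so analytic values are preferred wherever they
  exist and finite differences are demoted to test oracles.
* `mu` (mutation, imitation rules only): per update event, the focal
  individual adopts a uniformly random strategy with probability `mu`.
  `mu = 0` gives the absorbing chains used for fixation probabilities;
  the small-mutation stationary route uses `mu = 1e−3`.

## Synthetic networks: what they emulate and what they do not

All inputs are generated in-package; there are no external data. The
generators mirror the standard study conditions for this class of models:

* `random_graph()`: Erdős–Rényi `G(N, p)` with `p = k̄/(N−1)`, redrawn
  until connected (connectivity is required so the dynamics reach every
  vertex). The literature this models rarely names its random-graph
  constructor; G(N, p) is the default choice and is stated here as ours.
* `random_regular()`: uniform random `k`-regular simple graphs.
* `scale_free()`: Barabási–Albert preferential attachment with
  `m = round(k̄/2)`, again a stated reconstruction of "scale-free network".
* `assign_weights()`: per-edge i.i.d. weights — all ones, uniform on the
  integers 1..10, or Zipf with exponent 3. The discrete power law needs a
  support decision; it is truncated at 100 and renormalized, which keeps
  all moments finite and the dynamics numerically tame while preserving
  the heavy-tail contrast with the uniform scheme.
* `enumerate_connected_graphs()`: exact exhaustive enumeration up to
  isomorphism (all `2^(n(n−1)/2)` labeled graphs, connectivity filter,
  BLISS canonical-form deduplication), guarded at `n ≤ 7`.

Passing tests on these graphs demonstrate the *structural* universality
claims — invariance across topologies, weight distributions, and
update-function assignments. They do not show anything about empirical
social networks beyond that: real interaction networks are temporal,
directed, weighted by processes far from i.i.d. edge draws, and human
updating need not be stationary aspiration-driven switching. The package
deliberately models none of that (fixed graphs, fixed aspirations, no
learning).

## Numerical choices

* Stationary distributions are computed by a direct linear solve — one row
  of `Pᵀ − I` replaced by the normalization row — dense below 4096 states,
  sparse LU above; never power iteration. This is deterministic and exact
  to solver precision; the result is validated against `uᵀP = uᵀ` at 1e−10
  and clamped of `−0`-level negatives only below 1e−12.
* The chain builder refuses `n > 20` (and the imitation builder `n > 16`),
  keeping `2^n` within memory; the test and acceptance workloads use
  `n = 6` (the full 112-graph catalogue; seconds per sweep), `N = 100` for
  the Monte Carlo crossing experiment, and spot checks up to `N = 1000`
  for generator statistics.
* Finite-β crossings: bisection on `⟨x_A⟩(a) − 1/2` with bracket
  `a* ± 5` and tolerance 1e−4, after verifying a sign change (monotonicity
  of the abundance in `a` is a precondition, checked at the bracket ends).
  The margin route instead exploits exact affinity of the margin in `a`
  and solves from two probes — no tolerance at all.
* Ties: `winner` is declared `tie` only when the margin is below 1e−12
  relative; the boundary game `a + b = c + d` lands there exactly because
  the closed form is evaluated in floating point on a balanced sum.
* Monte Carlo: one time step is one focal update attempt; the focal
  payoff is recomputed from the live state each step (no stale caches).
  The compiled (Rcpp) and pure-R engines consume an identical
  two-draws-per-step RNG stream and are tested to produce the same
  trajectory to summation rounding. Standard errors use batch means (100
  batches) to respect autocorrelation; each run starts from a
  uniform-random strategy word, a choice that the neutral symmetry of the
  stationary average makes immaterial and that we state rather than infer.

## Imitation rules as reconstructions

The comparison dynamics are deliberately conventional reconstructions:
pairwise comparison uses the same `g` family on payoff differences
(`f_l(β(π_j − π_l))`, neighbor sampled by edge weight), death–birth uses
exponential fitness `exp(β π)`, and symmetric mutation resamples the
updated strategy uniformly with probability `μ`. Their success criterion in
the rare-mutation limit compares vertex-averaged single-mutant fixation
probabilities `ρ_A` and `ρ_B`, the latter by strategy relabeling (mirrored
payoff matrix) rather than a second code path. Two independent routes to
the imitation critical payoff — the `μ → 0` fixation route and a
small-but-explicit-mutation stationary route — are both exposed and agree
within 0.1 on six-vertex graphs in the test suite. Because the precise
printed definitions of these rules (and the σ formulas attached to them)
live outside what this package treats as normative, the cross-rule results
are asserted as properties (nonzero spread across graphs, sensitivity to a
single deviating update function, `σ ≠ 1` on the six-cycle), never as
point values.

## Known limitations

* Everything analytic is first order in `β`; at strong selection only the
  direct finite-β solves (exact for `n ≤ 20`) apply, and no `β²` terms are
  computed.
* Degenerate update functions with `g(0) → 0` freeze the neutral chain;
  the constructors reject them, and the closed forms would diverge with
  them (the `1/(2g_l(0))` factors).
* Enumeration beyond seven vertices is out of reach of the exhaustive
  strategy by design; the catalogue approach targets the small-`n`
  universality experiments.
* The birth–death rule and symbolic σ expressions for imitation rules are
  intentionally absent.
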