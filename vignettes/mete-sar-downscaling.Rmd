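---
title: "Downscaling species-area relationships with maximum entropy: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downscaling species-area relationships with maximum entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metesar)
```

## The model

The Maximum Entropy Theory of Ecology (METE) treats a community as a
constrained inference problem: among all probability distributions
consistent with a handful of measured state variables, choose the one of
maximum entropy. For spatial downscaling of richness, two distributions
carry the whole theory.

**Spatial occupancy.** For a species with `n0` individuals in a plot of
area `A0`, the probability that `n` of them fall in a quadrat of area `A`
is constrained only by its mean, `E[n] = n0 A / A0`, and its support
`0..n0`. The MaxEnt solution is a truncated geometric,

$$\Pi(n \mid A, n_0, A_0) = \frac{x^n}{Z_\Pi}, \qquad
  Z_\Pi = \sum_{m=0}^{n_0} x^m, \qquad x = e^{-\lambda_\Pi},$$

with $\lambda_\Pi$ fixed by the mean constraint

$$\frac{n_0 A}{A_0} \;=\; \frac{x}{1-x} - \frac{(n_0+1)\,x^{n_0+1}}{1-x^{n_0+1}}.$$

At exactly half area the multiplier vanishes and
$\Pi(n) = 1/(n_0+1)$: every allocation of `n0` individuals between two
equal halves is equally likely. Iterating this flat rule one halving at a
time yields the recursion

$$\Pi_i(n) = \sum_{q=n}^{n_0} \frac{\Pi_{i-1}(q)}{q+1},$$

which is the occupancy law of the HEAP model (Hypothesis of Equal
Allocation Probabilities). The package exposes both routes:
`occupancy_pmf_direct()` solves the constraint at any area fraction in
$(0, \tfrac12]$; `occupancy_pmf_recursive()` iterates the halving rule.

**Abundance.** If the empirical abundance vector is not supplied, MaxEnt
with the constraint "mean individuals per species = `N0/S0`" and upper
bound `N0` yields a truncated log-series,

$$\Phi(n \mid N_0, S_0) \propto \frac{x^n}{n}, \qquad n = 1..\lfloor N_0\rfloor,$$

solved by `solve_sad()`. The metabolic-rate side of the full theory never
enters: richness predictions are unchanged by ignoring it, so the package
does not model it.

**Expected richness** at relative area $a$ is the summed occupancy
$\sum_j (1 - \Pi(0 \mid a, n_{0,j}))$, or its expectation under $\Phi$
when abundances are predicted rather than observed. Crossing
{direct, recursive} occupancy with {observed, theoretical} abundances
gives the four variants of `predict_all_variants()`. The recursive-
theoretical variant is the only one that re-solves its SAD while
descending: each halving produces predicted state variables
$(S_{i+1}, N_{i+1}) = (S_i \sum_n \tfrac{n}{n+1}\Phi(n \mid N_i, S_i),\; N_i/2)$
that constrain the next step. Fractional $S$ and $N$ are carried as reals
throughout and never rounded; if the predicted state degenerates
($S < 1$, $N < S$, or an unreachable SAD mean), the curve is truncated
with a diagnostic rather than extrapolated.

## Conventions the theory leaves open

Two points are ambiguous in the theory as usually stated; the package
fixes both by convention, asserted by tests.

**Richness "at half area".** The recursive richness expressions can be
read as evaluating the vacancy either at $A_0/2$ (one application of the
flat rule) or one bisection deeper. The package uses the former: richness
at depth 1 employs the vacancy $1/(n_0+1)$. This is forced by
self-consistency — $\lambda_\Pi = 0$ at $a = \tfrac12$ makes the direct
and recursive forms identical there — and gives the depth-1 coincidence
property: within each abundance source, recursive and non-recursive
variants agree exactly at one bisection. Note the coincidence is *within*
a SAD source only; theoretical and observed variants differ at every
depth whenever $\Phi$ differs from the empirical abundance distribution,
as it must.

**The sign of the SAD exponent.** A truncated log-series with
$x \le 1$ cannot have mean abundance above $M/H_M \approx N_0/\log N_0$
($H_M$ the harmonic number). Species-poor but individual-rich communities
— dense grasslands, species-poor woodlands with
$N_0/S_0 > N_0/\log N_0$ — therefore require $x > 1$, i.e. a negative
log-series exponent, a legitimate regime of the theory. `solve_sad()`
brackets the multiplier in $(0, \infty)$ and rejects only a mean pinned
at or above the truncation point, which no finite multiplier reaches.

## Numerics

* **Occupancy multiplier.** Root finding happens in
  $\lambda \in [0, \infty)$, where the constraint mean
  $m(\lambda) = 1/\mathrm{expm1}(\lambda) - (n_0+1)/\mathrm{expm1}((n_0+1)\lambda)$
  is strictly decreasing, so 90 safeguarded bisections from the bracket
  $[0, \log(1 + 1/(n_0 a))]$ converge to machine precision. The two
  `expm1` terms cancel catastrophically near $\lambda = 0$ (the half-area
  limit); for $(n_0+1)\lambda < 10^{-4}$ a series expansion
  $m \approx n_0/2 - \lambda\, n_0(n_0+2)/12$ takes over. The solver is
  vectorised over `n0` because the non-recursive theoretical variant
  needs the multiplier for every abundance class `1..N0` (up to $2\times
  10^5$) at every depth; a scalar root finder per class would be two
  orders of magnitude slower with no accuracy gain.
* **Upscaling is rejected.** Area fractions above $\tfrac12$ require
  $\lambda < 0$; the evaluation protocol never uses them and the solver
  raises a domain error. Arbitrary fractions below $\tfrac12$ (not only
  powers of 2) are accepted by the direct route.
* **SAD sums** are computed in log space with max-subtraction, so tails
  underflow gracefully for either sign of the exponent. An optional
  `truncate_tail` flag drops abundance classes beyond cumulative mass
  $1 - 10^{-9}$; the default keeps the exact support.
* **Tolerances** (package constants): solved-constraint relative
  residual $10^{-10}$, pmf normalisation $10^{-10}$, plot aspect-ratio
  check $10^{-6}$.
* **Grid membership.** Nested quadrats use half-open intervals
  `[lo, hi)` with the plot's maximum edge closed, so every stem is
  counted exactly once at every depth — conservation is testable, not
  assumed. Bisection always splits the longer side; squares split across
  x. Empty quadrats contribute richness 0 to the per-depth mean: the full
  `2^i` grid is the Type IIA sample, not its occupied subset.

## What the synthetic generator does and does not emulate

The generator exists so the whole pipeline is testable without access to
census data, which is rarely redistributable. Its stated world:

* **Abundances** follow the solved log-series via deterministic
  quantile spacing (`expected_sad_abundances()`), nudged by unit
  increments on the most abundant ranks so `S` and `N` are conserved
  exactly. Real SADs scatter around the log-series; the generator
  deliberately does not add that scatter, because the tests need the SAD
  assumption of the theoretical variants to hold exactly.
* **Placement** spans the aggregation axis the variant comparison turns
  on: `random` (complete spatial randomness), `heap` (the bisection
  allocation process whose quadrat occupancy is *exactly* the recursive
  law — the generative–analytic loop closes, and the test suite closes
  it), and `thomas` (cluster process; offspring wrap toroidally to avoid
  edge-density artifacts). Heap splitting depth defaults to 8 and should
  be set to the analysis depth so generated data match the recursive
  model at every evaluated scale.
* The default benchmark suite spans `S0` 7–301 and `N0` 669–205096 —
  the state-variable ranges of published stem-mapped vegetation plots —
  on square and 2:1 extents.

What it does not emulate: dispersal-driven interspecific correlation,
habitat heterogeneity, size structure, measurement error in species
identification, or irregular plot boundaries. A green synthetic test
therefore establishes internal correctness (the code computes the theory
it claims) and directional behaviour (non-recursive beats recursive under
CSR; the ordering can invert under strong clustering), not empirical
adequacy on any real forest.

## Evaluation choices

Observed and predicted SARs are paired per depth and scored with
$R^2$ about the 1:1 line on log values — relative, not absolute,
deviations matter across the orders of magnitude a SAR spans. The
logarithm base is immaterial (both sums rescale identically; asserted to
$10^{-12}$) and base 10 is used. Depth-0 pairs are excluded by default
because both sides equal `S0` identically — including them inflates every
score — but `include_depth0 = TRUE` restores them and the choice is
recorded in the result object. Pooled rankings concatenate all sites'
pairs per variant rather than averaging per-site scores; ties order
alphabetically by variant label.

## Limitations

* Downscaling only: upscaling (`A > A0/2`) and the universal
  slope–`N/S` relationship are out of scope.
* The occupancy model is spatially implicit — it carries no
  between-quadrat correlation, so distance-decay patterns are outside the
  model class.
* Recursive predictions exist only at bisection scales `A0/2^i`; the
  nested-grid protocol requires square or 2:1 plots (carve subplots from
  anything else with `extract_subplots()`).
* The recursive-theoretical curve can truncate before the requested
  depth on small or sparse communities; downstream code must handle
  shorter curves (the evaluation layer pairs only available depths).
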