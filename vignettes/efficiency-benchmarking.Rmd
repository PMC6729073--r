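---
title: "Benchmarking care-facility efficiency: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking care-facility efficiency: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcfdea)
```

`ltcfdea` implements a two-stage efficiency analysis for sets of comparable
service units — the motivating application is long-term care facilities
(LTCF), each described by six inputs (fixed assets, four staff categories,
beds) and six outputs (resident counts by care need, and three
quality-of-care rates where lower is better). Stage one benchmarks every
decision-making unit (DMU) against an empirical best-practice frontier by
data envelopment analysis (DEA); stage two regresses the resulting scores on
facility covariates with a two-limit Tobit model. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
package's synthetic-data tests do and do not establish.

## Stage one: the DEA models

### Radial envelopment (CCR / BCC)

For DMU $o$ with inputs $x_o \in \mathbb{R}^m_{>0}$ and outputs
$y_o \in \mathbb{R}^s_{\ge 0}$, the input-oriented envelopment program is

$$\min_{\theta,\lambda,s^-,s^+} \theta
\quad\text{s.t.}\quad
X^\top\lambda + s^- = \theta x_o,\;\;
Y^\top\lambda - s^+ = y_o,\;\;
\lambda \ge 0,\; s^\pm \ge 0,$$

with the convexity constraint $\sum_j \lambda_j = 1$ added under variable
returns to scale (the BCC model; without it, CCR). $\theta^* \in (0,1]$ is
the fraction of observed inputs that would suffice to produce the observed
outputs on the frontier. A DMU is *fully* (strongly) efficient only when
$\theta^* = 1$ **and** all slacks are zero.

Textbook statements of this program attach a non-Archimedean penalty
$\varepsilon(e^\top s^- + e^\top s^+)$ to the objective. Giving
$\varepsilon$ a numeric value distorts scores, so the package uses the
standard lexicographic two-phase scheme instead: phase one minimises
$\theta$; phase two fixes $\theta^*$ and maximises the total slack. The
reported slacks are therefore the maximal ones, and "fully efficient" is
decided exactly as the $\theta=1,\ s^-=s^+=0$ condition demands. One
consequence worth knowing: the phase-2 objective (a raw sum of slacks in
mixed units) is itself not units-invariant, which is the standard trade-off
of the two-phase method; scores and the efficient/inefficient verdict are
units-invariant, and that is what the tests assert.

The decomposition is `TE = PTE × SE`: TE is the CCR score, PTE the BCC
score, and scale efficiency SE = TE/PTE measures the loss from operating
away from the most productive scale size. Since the CRS frontier envelops
the VRS frontier, SE ≤ 1 always.

### Returns-to-scale classification

The textbook rule classifies returns to scale from $\sum_j \lambda_j^*$ in
the CCR model: below 1 increasing (IRS), above 1 decreasing (DRS), equal to
1 constant (CRS). When the optimal $\lambda$ is not unique this is
ill-defined — different optimal vertices can give different sums. The
package therefore computes the interval
$[\min \sum\lambda,\ \max \sum\lambda]$ over the whole CRS optimal face (two
secondary LPs with $\theta$ fixed at $\theta^*$) and labels CRS when the
interval contains 1, IRS when it lies entirely below, DRS entirely above.
The classification is deterministic and independent of solver vertex
choice; interval endpoints are compared against 1 with tolerance
$\sqrt{\texttt{tolerance}}$ to absorb LP round-off.

### Slacks-based measure and super-efficiency

The radial score ignores residual slacks, so it overstates efficiency for
DMUs with a wasteful input *mix*. The input-oriented SBM score

$$\rho = \min\; 1 - \frac{1}{m}\sum_{i=1}^m \frac{s_i^-}{x_{io}}
\quad\text{s.t.}\quad X^\top\lambda + s^- = x_o,\; Y^\top\lambda \ge y_o,\;
\lambda \ge 0$$

penalises every individual input excess; in this orientation the objective
is linear, so a single LP suffices (no Charnes–Cooper fractional transform
is needed). Always $\rho \le \theta$, with equality exactly when the radial
projection leaves no slack; the sets $\{\rho = 1\}$ and
$\{\theta = 1,\ s^\pm = 0\}$ coincide, which the property tests verify.

Efficient DMUs all score 1 and cannot be ranked. The super-efficiency SBM
program excludes DMU $o$ from its own reference set and measures how far
its inputs could grow while remaining dominated:
minimise $\frac{1}{m}\sum_i \bar x_i / x_{io}$ subject to
$\bar x \ge X_{-o}^\top\lambda$, $Y_{-o}^\top\lambda \ge y_o$,
$\bar x \ge x_o$. The score is ≥ 1 for efficient units; inefficient units
keep $\rho$, so all DMUs rank on one scale (ties broken by dataset order).
Whether a published ranking of this kind uses the super-score or some other
tie rule is usually unstated; the convention above is this package's
documented contract. Under VRS the exclusion can make the program
infeasible (always for $n=1$); the score is then `Inf` with a warning — the
conventional sentinel for an unbeatable unit, which simply ranks first.

### Undesirable outputs

Quality indicators such as fall rates are outputs where lower is better.
The default treatment replaces each such column $u$ by
$u' = \max_j(u_j) + \kappa - u_j$ with $\kappa = 1$ on the column's own
scale: a strictly decreasing map that preserves shape and units, and leaves
BCC input-oriented scores invariant (output translation invariance under
the convexity constraint). Under CRS, translation does change scores — no
monotone shape-preserving treatment avoids that — so the package records the
transform in the dataset's metadata and refuses to solve untransformed
data. The alternative convention, moving undesirable outputs to the input
side (`method = "input"`), is available behind the same interface.
$\kappa$ matters only through the transformed column's minimum (it keeps it
strictly positive); 1 unit is the natural choice for percentage-scale
indicators.

### Projections and adjustment tables

The frontier target for an inefficient DMU is $x_o - s^-$ (SBM) or
$\theta^* x_o - s^-$ (radial); re-solving at the projected point returns a
score of 1, which the tests check to $10^{-5}$. The adjustment table
reports, per input indicator, the amount `NA = actual − projection` and the
proportion `NA / actual × 100%`, plus an arithmetic mean row — the layout
used in published slack analyses of the DRS subset. The denominator is
fixed as the *actual* value: published tables of this form are internally
consistent with that reading (a facility cut from 8 to 1 administrative
staff shows 87.50%), even where their prose suggests otherwise. Whether
such tables derive from SBM or radial phase-2 slacks is often ambiguous;
the `source` argument allows either, with SBM the default.

## Stage two: the two-limit Tobit model

Efficiency scores live in $(0,1]$ and pile up at 1, so ordinary least
squares on covariates is biased. The package fits the censored-normal model
$y^* = x^\top\beta + e$, $e \sim N(0,\sigma^2)$, $y = \min(\max(y^*,L),U)$
with limits $(L,U) = (0,1)$ by default, maximising the exact two-limit
likelihood (normal density for interior points, normal tail probabilities
at the limits). Scores of this kind are often described as "truncated", but
observations *at* the boundary are censored, not discarded — hence the
censored likelihood. When the dependent variable is a super-efficiency
score (which exceeds 1), set the upper limit to `Inf`.

Numerics: BFGS over $(\beta, \log\sigma)$ with the analytic gradient, from
an OLS start; convergence failure is an error, never a silent result.
Standard errors come from the inverse observed information at
$(\hat\beta, \hat\sigma)$, computed by differencing the analytic gradient
with scale-aware steps, so they are equivariant under covariate rescaling
to about $10^{-6}$. Wald p-values use the normal reference; the
likelihood-ratio statistic against the intercept-only null (fitted on
identical data and limits) is reported alongside, and its chi-square
calibration is verified by simulation: at $n = 200$ the empirical type-I
error over 1000 replicates sits inside [0.03, 0.07].

McFadden's pseudo-$R^2 = 1 - \ell_{\text{full}}/\ell_{\text{null}}$ is a
proportion only while both log-likelihoods are negative; with a continuous
response and small $\sigma$, log-likelihoods are routinely positive and the
ratio can exceed 1 (published Tobit tables occasionally show such values).
The package reports the statistic as defined and leaves interpretation to
the analyst.

Degenerate inputs are refused with named errors: all observations censored
(no information about $\sigma$), collinear covariates (named), too few
observations. A fit stores the sum of censoring counts, which always equals
$n$.

## The LP core

No linear-programming backend is assumed: the envelopment programs are tiny
(a 32-DMU, 6+6-indicator analysis solves LPs with ~45 variables and 13
rows), so the package carries a dense two-phase primal simplex with Bland's
anti-cycling rule. Bland's rule trades speed for guaranteed termination
under the heavy degeneracy typical of DEA programs; at these sizes the
trade is free (a full 32-DMU analysis runs in well under a second). Pivot
entries below `tolerance × 0.01` are treated as zero; phase-1 residuals
above `tolerance` (default $10^{-7}$) signal infeasibility. The test suite
cross-checks the solver against an independent brute-force oracle that
enumerates every basic point of the constraint system — on 200 random
instances (n ≤ 6, m+s ≤ 4) the worst disagreement is below $10^{-13}$,
far inside the $10^{-5}$ acceptance band.

## The synthetic-data generators

Three generators make every stage testable with known ground truth:

* `simulate_frontier()` builds a **ray technology**: frontier DMUs are
  positive scalings of one base input-output mix, and each inefficient DMU
  is a frontier point with all inputs multiplied by a factor $f \ge 1$, so
  its true CRS input-oriented TE is exactly $1/f$. This is the one
  construction with a closed-form truth, which is why the generator refuses
  to build a multi-mix VRS frontier (there the "truth" would itself be
  solver-defined, and the test would be circular).
* `simulate_ltcf()` draws the twelve indicators from log-normal bodies
  matched to the published per-column mean/SD of the 32-facility study and
  truncated to the published ranges — log-normal because several columns
  show SD above their mean (strong right skew). Only the two ranges that
  are unambiguous in the source (caregivers 10–115, beds 24–300) are
  enforced as hard clips and asserted in tests; after truncation the beds
  mean sits within a few percent of the published 80. Covariates mirror the
  published structure: ~7 public / 25 private per 32, ~22 urban / 10 rural,
  occupancy centred near 47%.
* `simulate_tobit()` generates censored scores from a known
  $(\beta, \sigma)$ with exact censoring at the limits; the upper-censoring
  fraction matches the closed-form normal tail probability.

What these tests *show*: the solvers recover planted efficiencies to
$10^{-6}$, the estimator recovers planted coefficients within sampling
error, and every invariance the models promise holds on random data. What
they *do not* show: the indicators of `simulate_ltcf()` are drawn
independently across columns, so they carry none of the input-output
correlation structure of real facilities; synthetic efficiency
distributions therefore do not mimic the published score distribution, and
no test pretends they do. The published per-DMU results ship as verbatim
fixtures (`ltcf_table3()`, `ltcf_table4()`) precisely because the raw
32-facility matrix is not public and those numbers cannot be recomputed.

## Problem sizes and tolerances used by the tests

Oracle equivalence uses 200 random instances at n ≤ 6, m + s ≤ 4 (the
brute-force oracle is exponential in problem size, so small instances are
the point, not a concession); frontier recovery uses 100 DMUs; Tobit
recovery uses n = 5000 and the LR calibration 1000 replicates at n = 200.
Score comparisons against the printed tables use absolute tolerance
5×10⁻⁴ (3-decimal printed precision); solver-vs-oracle 10⁻⁵; invariances
10⁻⁶.

## Known limitations

* Input-oriented models only; output-oriented and non-oriented variants,
  window/Malmquist analysis and weight-restricted DEA are out of scope.
* The undesirable-output translation is a convention, not a theorem; under
  CRS the scores depend on it, and the treat-as-input alternative gives
  different (also defensible) numbers.
* Two-stage DEA-plus-Tobit ignores the sampling noise in first-stage
  scores; bias-corrected bootstrap procedures exist but are deliberately
  not implemented.
* The simplex core targets small dense programs; for thousands of DMUs a
  sparse LP backend would be the right tool.
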