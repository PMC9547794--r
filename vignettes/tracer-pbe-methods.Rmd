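---
title: "Methods: sectional schemes for the tracer-mass aggregation population balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sectional schemes for the tracer-mass aggregation population balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbesim)
```

## The model

Granulation and crystallization experiments often label a subset of the
material with a tracer and follow how the tracer redistributes over granule
sizes as particles aggregate. The two-property description (granule volume
$v$ and tracer content $x$) reduces, after integrating out the tracer
coordinate, to two coupled one-dimensional population balances on a truncated
volume domain $(0, v_{\max}]$: one for the number density $f(t, v)$,

$$\partial_t f = \tfrac12\int_0^v \beta(v-\eta, \eta)\, f(v-\eta) f(\eta)\,
  d\eta - f(v) \int_0^{v_{\max}} \beta(v, \eta) f(\eta)\, d\eta,$$

and one for the tracer mass density $m(t, v)$,

$$\partial_t m = \int_0^v \beta(v-\eta, \eta)\, m(v-\eta) f(\eta)\, d\eta
  - m(v) \int_0^{v_{\max}} \beta(v, \eta) f(\eta)\, d\eta.$$

The tracer birth integral carries no $\tfrac12$: by symmetry of the
convolution it already counts the tracer inherited from both parents of a
newborn granule, and only with this normalization is the total tracer mass
$\int m\,dv$ invariant under aggregation. $\beta(v,\eta) = \beta_0
\beta^*(v,\eta)$ is the aggregation kernel; the package implements the
constant ($\beta_0$), additive ($\beta_0(v+\eta)$, gelling only in continuous
systems) and multiplicative ($\beta_0 v\eta$, always gelling) families.

In the MSMPR (mixed-suspension mixed-product removal) extension both
equations gain a washout sink $-\,\cdot/\tau$ and the number equation a
nucleation source $B_0\delta(v)$. Nuclei carry **no tracer**: the printed
tracer equation of the source problem shows a $+B_0\delta(v)$ term, but the
companion exact result $m_T = m_0 e^{-T}$ (pure washout decay of total
tracer) admits no tracer source, so the source is treated as typographical.
Likewise the tracer pulse initial condition is read as $m(0, v) = m_0
\delta(v - v_0)$.

## Discretization

The domain is split into $I$ cells with edges $v_{i\pm 1/2}$ and
representative volumes $v_i$; all particles of a cell are treated as
concentrated on its representative (point-mass ansatz). The central object is
the pair index set

$$\Upsilon^i = \{(j,k):\ v_{i-1/2} < v_j + v_k \le v_{i+1/2}\},$$

half-open and upper-inclusive (a sum landing exactly on an edge belongs to
the lower cell). The finite-volume scheme (FVS) is then

$$\frac{dm_i}{dt} = \sum_{(j,k)\in\Upsilon^i} \tfrac12\beta(v_j, v_k)
  (m_j N_k + m_k N_j) - m_i \sum_{j=1}^I \beta(v_i, v_j) N_j,$$

with the analogous number scheme ($\tfrac12\beta N_j N_k$ births). Birth
pairs with $v_j + v_k > v_{\max}$ are dropped (domain truncation); the death
sum always runs over all cells. Summing the scheme over $i$ makes every birth
cancel a death term, so total tracer mass is conserved **identically**
whenever all active pairs are in-domain — this is the scheme's defining
structural property and the package's primary run diagnostic
(`max_conservation_drift`).

### Grid convention

The geometric grid honors the representative rule exactly,
$v_i = v_1\, 2^{(i-1)/p}$, because the representatives determine where pair
sums land and hence the whole scheme. Interior edges are arithmetic midpoints
of adjacent representatives, $v_{1/2} = 0$, and the last edge extrapolates the
midpoint sequence by the grid ratio $2^{1/p}$, which defines $v_{\max}$. (The
two textbook rules — representatives as edge midpoints, and a pure geometric
progression — are mutually inconsistent once $v_{1/2} = 0$; keeping the
progression exact is standard sectional practice and, for $p = 1$, makes
equal pairs land exactly one cell up, $2 v_j = v_{j+1}$.) The benchmark cell
counts (23/67/110 for the additive runs, 21/61/101 for the multiplicative
ones at $p = 1, 3, 5$) define the grids; $v_{\max}$ follows from them
($\approx 4\times 10^6$) and is recorded in run metadata. Nominal domain
sizes of a few hundred quoted alongside those counts are not realizable by a
ratio-$2^{1/p}$ grid from $v_1 = 1$ and are ignored in favor of the counts,
which scale consistently across $p$.

### The cell average comparator

The cell average technique (CAT) is implemented at contract level as the
reference method: per cell it accumulates newborn number, volume and tracer
rates, forms the average newborn volume $\bar v_i$, and splits the births
between the cell's representative and the neighbor on the side of $\bar v_i$
with the linear weights $\lambda = (\bar v - v_{far})/(v_{near} - v_{far})$
that preserve newborn number and volume exactly. Tracer births reuse the
number-derived weights (the source material does not specify the tracer
treatment; preserving the number-selected properties is our reading, and the
redistribution then conserves total tracer because the weights sum to one).
Cells with newborn tracer but zero newborn number have no defined average and
are skipped; at the domain boundary the average is clamped to the outermost
representative (one-sided redistribution). CAT and FVS share identical
cell-summed birth and death totals — they differ only in *placement* — which
is asserted by tests. Values are never clipped, so the comparator can exhibit
the negative-value pathology it is known for.

## Time integration

The sectional systems are stiff: death-rate coefficients grow like
$\beta(v_{\max}, \cdot)$, i.e. up to $\sim 10^6$ ($10^{13}$ for the product
kernel) on the benchmark grids, while the dynamics of interest evolve on
$O(1)$ times. No stiff ODE solver package is available in the target
environment, so the package ships its own integrators:

* `adaptive_stiff` (default): an L-stable 2(3)-order Rosenbrock method
  (ode23s-type coefficients) with step-doubling error control
  (`rtol = 1e-8`, `atol = 1e-10` by default). The FVS supplies its exact
  analytic Jacobian (the rates are quadratic forms over the pair sets); CAT
  uses a central finite-difference Jacobian, which is exact for the quadratic
  terms and only approximate through the slowly varying redistribution
  weights. For the tracer transient over a frozen steady number field the
  system is linear and the Jacobian is factored once.
* `rk45`: adaptive Dormand–Prince 5(4), used for non-stiff validation runs
  and as a cross-check path in the tests.
* `explicit_euler`: the textbook fixed-step update, retained because it is
  the printed form of the scheme. When no `dt` is given, drivers cap it at
  $0.5/\max_i(\text{death coefficient})$ of the initial state, which keeps
  the update positivity-preserving.

N and m are integrated as one concatenated system (the tracer right-hand
side needs the concurrent number field), avoiding splitting error.

Batch runs stop at a target degree of aggregation
$I_{agg} = 1 - \mu_0(t)/\mu_0(0)$ via an event located by linear
interpolation within the accepted step, making the stop time solver-choice
independent to $O(h^2)$.

### Gel detection

Product-kernel (and continuous additive) systems gel: volume escapes to
arbitrarily large sizes and, in the truncated system, flows out through
$v_{\max}$. The driver refuses to integrate past a detected gel point,
defined as a loss of more than 10% of the **total tracer mass**. The number
field's first moment $\sum v_i N_i$ is deliberately *not* used as the
monitor: sectional binning moves every newborn from $v_j + v_k$ onto a
representative, perturbing that moment on coarse grids even without gelation
(on the $p=1$ product preset it falls 10% long before the target
$I_{agg} = 0.5$ is reached). Total tracer mass, by contrast, is conserved
identically by the scheme except for genuine outflow through the domain top,
making it the clean gel-flux signal.

## MSMPR driver

`compute_steady_state()` marches the number system from an empty crystallizer
for 30 residence times at relaxed tolerance, then polishes the stationary
balance with damped Newton iterations on the analytic (FVS) or
finite-difference (CAT) Jacobian until
$\lVert dN/dt\rVert_\infty < 10^{-9}$. The steady-state degree of
aggregation $1 - \mu_0/(B_0\tau)$ is an **outcome**, reported as attribute
`iagg_ss`, never an input.

`run_msmpr_tracer()` injects the pulse into the cell containing $v_0$ and by
default holds the number field at the converged steady state (it is
stationary; re-integration is available via `reintegrate_N = TRUE` and is
tested to leave it in place). Tracer then obeys
$d(\textstyle\sum m_i)/dt = -\sum m_i/\tau$ exactly in the semi-discrete
system, so $m_T = m_0 e^{-T}$ is reproduced to solver tolerance — a
structural property, not an accuracy statement about the distribution.

### The operating point

The benchmark operating points $I_{agg} = 1/6$ (additive) and $1/10$
(product) cannot emerge from an all-ones parameter set
($\beta_0 = B_0 = \tau = v_0 = 1$): the steady moment balance
$B_0 = \mu_0/\tau + \text{(aggregation loss)}$ then pins the operating point
near $1/2$, outside the admissible range of the closed-form mean-volume
solutions ($I_{agg} < 1/3$ resp. $\le 1/8$). Both printed operating points
imply the *same* aggregation-to-washout ratio,
$\beta_0 = I/((1-I)\tau\mu_1) = 0.2$ (additive) and
$\beta_0 = 2I/(B_0 v_0^2 \tau^2) = 0.2$ (product), so the MSMPR presets use
$\beta_0 = 0.2$ — derived a priori from the printed operating points, not
fitted to any simulation output. With it the emergent values are
$0.160/0.167$ (additive, $p = 1/3$) and $0.095/0.100$ (product), confirming
the reading.

## Exact references and the error statistic

For batch monodisperse starts the mean primary volume
$\bar\chi_r = \mu_2/\mu_1$ has the closed forms $e^{2t}$ (additive) and
$1/(1-t)$, $t < 1$ (product). For the steady MSMPR the tracer-weighted mean
volume $\hat\lambda_T = \sum v_i m_i / \sum m_i$ has closed forms
parameterized by the operating point (`exact_lambda_T()`), both equal to 1 at
$T = 0$ for every admissible operating point (property-tested).

The benchmark's relative-error statistic does not pin down its norm; both a
final-time relative discrepancy and a normalized discrete $L_2$ over the
output grid are provided (`relative_error(..., norm =)`). The recorded
convention for table reproduction is the normalized $L_2$ on
$T \in [0, 3]$ with 61 output points, against the closed form at the nominal
operating point.

### A documented inconsistency

The additive-kernel closed form prints the exponent $2I/(1-I)\,T$. The tracer
first-moment balance of the model as printed gives
$d\hat\lambda_T/dT = \beta_0\tau(\mu_1\hat\lambda_T + \mu_2)$, i.e. exponent
$\beta_0\tau\mu_1 = I/(1-I)$ — half the printed one — while the printed
*constant* term $(1-I)/(3I-1)$ equals the model's fixed point $-\mu_2/\mu_1$
exactly. Our FVS and CAT runs agree with each other and with this moment
closed form to the discretization level (2.5% at $p = 3$), and the
product-kernel closed form (which *is* consistent with the model — the same
balance reproduces its exponent $(1-\sqrt{1-8I})/2$ exactly) is matched by
CAT to 0.2% at $p = 3$. Consequently the published additive-kernel error
table cannot be reproduced by a faithful implementation of the printed
equations; the corresponding acceptance assertions are left failing at their
stated tolerances rather than loosened, with the analysis in the
maintainers' decision log.

## What the tests do and do not establish

The synthetic configurations are the benchmark's own stated worlds:
monodisperse unit-volume batch starts and pulse-plus-steady-state MSMPR
transients on geometric grids, with no measurement noise and no size
dependence beyond the three kernel families. Green tests therefore establish
structural correctness (binning partition, oracle equivalence at $10^{-12}$,
conservation at $10^{-6}$ or better, linear-grid equivalence with the
discrete Smoluchowski system, closed-form moment tracking) and the documented
accuracy of the schemes on those grids. They do not establish accuracy for
real granulation data, time-dependent or empirical kernels, breakage or
growth, or grids outside the geometric family.

Known limitations worth stating plainly:

* the FVS binning is first-order on coarse geometric grids and systematically
  diffusive for mean-volume metrics: batch additive errors in
  $\hat\lambda_T$ at $I_{agg} = 0.8$ are 80%, 27%, 10.6%, 3.9%, 2.7% at
  $p = 1, 3, 5, 8, 12$ — measured by the package's own convergence runs, and
  the reason one published 5%-band assertion at $p = 5$ is left failing;
* because CAT preserves newborn volume while pure binning does not, CAT is
  the *more* accurate scheme for mean-volume metrics on coarse grids in this
  implementation; the opposite published ordering could not be reproduced
  from the printed equations;
* CAT negativity on the coarse product-kernel batch appears at the
  integration-noise scale (about $-4\times 10^{-10}$ with default
  tolerances) in tail cells, while the FVS field stays exactly nonnegative
  there; the qualitative contrast is robust, its magnitude is
  tolerance-dependent;
* $\mu_1$-type moments of the *number* field are not conserved by binning
  (only totals are), so number-based and tracer-based primary-particle
  metrics diverge on coarse grids.
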