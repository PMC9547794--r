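# pbesim

Sectional finite-volume schemes for tracer-mass aggregation population
balance equations, with batch and MSMPR crystallizer drivers.

## What problem this solves

In granulation and crystallization, labeling part of the material with a
tracer and following how the tracer mass redistributes over granule volumes
is a standard way to infer aggregation kinetics. The reduced two-property
model tracks a number density `f(t, v)` and a tracer mass density `m(t, v)`
through a pair of coupled Smoluchowski-type integro-differential equations.
`pbesim` is for process modellers who need to solve these equations
numerically on sectional (geometric) volume grids and benchmark the schemes
against the known closed-form solutions.

The package provides:

* **The finite-volume scheme (FVS)** — newborn granules are binned by the
  pair index sets `Υ^i = {(j,k): v_{i-1/2} < v_j + v_k ≤ v_{i+1/2}}`:

  `dm_i/dt = Σ_{(j,k)∈Υ^i} ½ β(v_j,v_k)(m_j N_k + m_k N_j) − m_i Σ_j β(v_i,v_j) N_j`

  plus the companion number scheme. Total tracer mass is conserved
  identically (births and deaths telescope).
* **The cell average technique (CAT)** as a reference comparator: per-cell
  newborn averages redistributed to neighboring representatives with
  number/volume-preserving weights.
* **Drivers**: batch runs stopped at a target degree of aggregation
  `I_agg = 1 − μ₀(t)/μ₀(0)` with gel guarding, and MSMPR (nucleation `B₀`,
  washout `1/τ`) steady states plus tracer-pulse transients.
* **Stiff integration**: a built-in adaptive L-stable Rosenbrock method with
  analytic Jacobians (plus RK45 and explicit Euler).
* **Exact references and error statistics**: `e^{2t}`, `1/(1−t)`,
  `m₀ e^{−T}`, the MSMPR tracer-weighted mean-volume closed forms, and the
  final-time / normalized-L2 relative-error conventions.
* **Brute-force oracles** (triple-loop right-hand sides, discrete
  Smoluchowski reference on the unit lattice) used by the test suite.

## Worked example

```r
library(pbesim)

# batch: additive kernel, geometric grid p = 3 (67 cells), run to I_agg = 0.8
res <- run_batch(batch_config("additive", p = 3, cells = 67, target_iagg = 0.8))
n <- nrow(res$metrics)
final <- particle_state(res$N[n, ], res$m[n, ], res$times[n])
tracer_weighted_mean_volume(final, res$grid)

# MSMPR: steady state with nucleation + washout, then a tracer pulse
cfg <- preset("msmpr-sum/p3")
steady <- compute_steady_state(cfg)
run <- run_msmpr_tracer(cfg, steady)
```

Output (as printed by this code):

```
stop time          : 1.6403 (exact ln 5 = 1.6094)
tracer mass drift  : 6.66e-16
lambda_T at stop   : 18.268 (exact e^(2t) = 26.591)
emergent I_agg     : 0.1669 (nominal 1/6 = 0.1667)
max |m_T - e^-T|   : 5.10e-07 over T in [0, 3]
```

Reading the numbers: the additive-kernel batch reaches 80% aggregation near
`t = ln 5` (the exact monodisperse value; the 2% offset is coarse-grid
binning error in the zeroth moment's driver `μ₁`). Total tracer mass is
conserved to machine precision — the scheme's structural property. The
tracer-weighted mean volume carries the scheme's known first-order
coarse-grid diffusion (errors shrink from 80% at `p = 1` to under 3% at
`p = 12`; see the vignette). On the MSMPR side, the emergent operating point
reproduces the nominal `I_agg = 1/6` to 0.2%, and the total-tracer decay
matches `m₀ e^{−T}` to solver tolerance because aggregation conserves tracer
and washout is linear.

## Command line

```sh
pbesim run --preset batch-sum/p1 --scheme fvs --out out/
pbesim run --config my_run.json --scheme cat --out out/
pbesim compare --presets msmpr-sum/p1,msmpr-sum/p3 --out out/
```

(`exec/pbesim` in the installed package; config schema documented in
`?load_config`.) `run` writes `states.csv`, `metrics.csv` and
`metadata.json`; `compare` emits an error table over schemes and grids.

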