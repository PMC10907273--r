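---
title: "A mass-action model of terazosin acting on phosphoglycerate kinase 1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-action model of terazosin acting on phosphoglycerate kinase 1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tzpgk)
```

## The question the model answers

Phosphoglycerate kinase 1 (PGK1) catalyses the first ATP-generating step of
glycolysis: reversible phosphotransfer from 1,3-bisphosphoglycerate
(1,3-BPG) to ADP, yielding 3-phosphoglycerate (3-PG) and ATP. Terazosin
(TZ), a quinazoline drug, binds PGK1's ADP/ATP pocket, so it should be a
plain competitive inhibitor — yet at nanomolar concentrations it *increases*
PGK1 activity, with inhibition appearing only at micromolar concentrations.
This package implements a mass-action kinetic explanation of that biphasic
dose–response: TZ binding to product-bound enzyme opens a bypass route that
circumvents the slow release of 3-PG, accelerating turnover at low TZ while
wholesale sequestration of the enzyme dominates at high TZ.

## The reaction network

The model tracks 10 enzyme configurations and 5 free ligands joined by 14
reversible mass-action reactions:

* a substrate diamond — E binds ADP and 1,3-BPG in random order to form the
  ternary complex E·ADP·BPG;
* a product diamond — E binds ATP and 3-PG in random order to form
  E·ATP·PG;
* reversible phosphotransfer E·ADP·BPG ⇌ E·ATP·PG;
* three TZ-bound forms (E·TZ, E·TZ·BPG, E·TZ·PG) reached by TZ occupying
  the vacant nucleotide pocket of E, E·BPG or E·PG.

Each reversible reaction `form_in + ligand ⇌ form_out` contributes the net
rate `kf·[form_in][ligand] − kr·[form_out]` (µM/s); internally all
concentrations are µM and time is in seconds. Rate constants come from
published stopped-flow measurements of substrate binding (pairs *a*–*d*),
reused for the chemically analogous product edges because product-side
constants were never measured. The phosphotransfer constants are unknown
and set symmetrically to 5 s⁻¹. Run `pgk_network()$reactions` to see every
edge with its resolved constants.

Two modelling choices deserve emphasis:

* **TZ rate assignment.** Only a dimensionless association multiplier
  η = 562 is specified for TZ. We scale the nucleotide association
  constants it competes with (η·a⁺ onto E, η·d⁺ onto E·BPG and E·PG) and
  reuse the corresponding nucleotide dissociation constants a⁻ and d⁻.
  Phosphoglycerate binding to E·TZ uses b±, as it does for any
  nucleotide-occupied enzyme. This assignment reproduces the reported
  93% TZ-bound enzyme at 25 µM TZ against 1 mM ADP competition.
* **No thermodynamic patching.** The measured constants do not satisfy
  detailed balance around the binding diamond
  (a⁺b⁺/a⁻b⁻ ≠ c⁺d⁺/c⁻d⁻). We keep them exactly as measured and impose no
  cycle-consistency correction; the model is driven and short-horizon, so
  equilibrium consistency is not required for its conclusions.

## Simulation protocol

The default `sim_config()` mirrors the in vitro experiment the model was
calibrated against: 0.04 µM PGK1 (all free), 1 mM ADP, no products, and
1,3-BPG *clamped* at 80 µM, emulating continuous regeneration by an
upstream coupled reaction. TZ is a dynamic, conserved species — at 2.5 nM
TZ versus 40 nM enzyme, depletion of free TZ is material, so clamping it
would be wrong. Clamping is a per-species flag (`set_clamped()`), which is
also what makes the linear steady-state cross-check below possible.

Integration uses the stiff solver `deSolve::lsoda` with rtol 1e-9 and
atol 1e-12 µM, tight enough that enzyme, adenine and TZ totals drift by
less than 1e-8 relative over a 60 s run (asserted in the test suite).
Integrator underflow below 1e-12 µM is clipped to zero; any larger negative
concentration raises an error instead of propagating.

**The production readout.** "ATP production" is the total
adenine-triphosphate pool — free ATP plus E·ATP plus E·ATP·PG — at 60 s, a
quasi-equilibrium time at which the production rate has reached and still
holds its maximum, so pool ≈ rate × 60 s (the pool at 30 s is 51.4% of the
pool at 60 s). An instantaneous-rate variant
(`atp_production(traj, kind = "rate")`, the net phosphotransfer flux) is
provided for sensitivity checks; both readouts give materially identical
dose–response ratios.

```{r}
net <- pgk_network()
dose_response(net)
```

The biphasic shape is the package's central reproduction: roughly +17% at
50 nM TZ and −90% at 25 µM TZ, with 50 nM the grid argmax and 25 µM the
argmin.

## Why: net fluxes and occupancy

`net_fluxes()` evaluates every interaction's forward-minus-reverse rate at
a state; `occupancy()` reports each configuration's share of total enzyme
and its change against the TZ-free baseline (TZ-bound forms, whose
baseline is zero, are reported as percent of total enzyme instead; a
baseline concentration under 1e-15 µM makes a percent change undefined and
is reported as `NA`). At 50 nM TZ the fluxes show a clockwise bypass
cycle: E·PG captures TZ (η·d⁺), E·TZ·PG releases 3-PG at the fast rate b⁻
instead of the slow c⁻, E·TZ reloads 1,3-BPG, and the enzyme re-enters the
substrate diamond. At 25 µM TZ the same strong association traps ~93% of
the enzyme in TZ-bound forms (~91% in E·TZ·BPG alone) and every net flux
collapses toward zero.

## The c⁻/b⁻ sweep

`sweep_parameter()` maps when TZ stimulates versus inhibits by varying one
rate constant — canonically c⁻, the slow 3-PG release, with b⁻ fixed at
160 s⁻¹ — and re-simulating a TZ-free baseline *at each swept value*
(the baseline depends on the parameter, so sharing one baseline would bias
every ratio). The default grid (`default_cminus_grid()`) is 25 log-spaced
points spanning c⁻/b⁻ from 0.005 to 1.2: wide enough to bracket the
stimulatory regime, the measured ratio 0.0875, and the inhibitory regime,
while keeping the full sweep (200 one-minute simulations) to seconds of
compute. `classify_stimulation()` labels each cell stimulation / neutral /
inhibition with a configurable neutral band (ε = 0.01 by default; the
figure this emulates does not state its own band).

Properties the sweep reproduces, all asserted in the tests: the ratio is
non-increasing in c⁻ at every dose; at c⁻/b⁻ = 1 no dose stimulates; and
setting d⁻ = 0 — so the ternary product complex can never release ATP
first, leaving no vacant pocket for TZ on the product side — eliminates
stimulation entirely, which is the bypass-entry argument in kinetic form.

One caveat the package's own analysis surfaces: at the *top* dose
(25 µM), the production ratio stays below one over the entire default
sweep range. Sub-micromolar and low-micromolar doses all stimulate
strongly at small c⁻/b⁻ (ratios 1.8–3.7 at c⁻/b⁻ = 0.005), but at 25 µM
the enzyme is ~93% sequestered regardless of c⁻, while the TZ-free
baseline always retains some recycling out of E·PG through ATP rebinding.
"All doses stimulate as c⁻/b⁻ → 0" therefore does not hold for this
parameterisation at the highest dose, and the corresponding acceptance
test records that fact rather than hiding it.

## The linear steady-state cross-check

With every free ligand clamped, the enzyme-form subsystem is linear,
`de/dt = M e`, with `M = enzyme_rate_matrix()` a generator matrix whose
null space (computed by SVD in `enzyme_steady_state()`) is the stationary
distribution. The test suite integrates the full nonlinear ODE path to
long times at randomized parameters and ligand levels — the horizon is set
from the slowest eigenvalue of `M` so every linear mode has fully
decayed — and requires component-wise agreement with the null-space
solution to 1e-6 relative error across 20 randomized settings. This checks
the ODE right-hand side, the integrator configuration and the clamping
machinery against closed-form linear algebra.

## The synthetic enzymatic assay

`generate_assay()` emulates the statistical structure of a coupled
spectrophotometric initial-rate assay: rates
`Vmax·S / (Km·(1 + I/Ki) + S)` plus additive homoscedastic Gaussian noise
(no noise model is stated for the real assay; homoscedastic additive is
the simplest defensible choice and the sd is configurable). It does *not*
model the coupled reporter enzyme mechanistically, absorbance calibration,
or substrate depletion during a measurement — so parameter-recovery tests
demonstrate correctness of the generator/fitter pair, not fidelity to any
real instrument. `fit_mm()` fits the hyperbolic form directly by bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`) — no double-reciprocal
linearisation — and reports asymptotic least-squares standard errors
(replicate-based errors would need a replicate design the emulation does
not define). Monte-Carlo tests confirm the estimator is unbiased within
10% at 5% noise and that asymptotic SEs agree with the Monte-Carlo spread
within a factor of two.

`predict_apparent_km()` runs the same fit on the *model's* early-time
production rates (the slope over 0.5–2 s: after the sub-second binding
transient, before product feedback matters; the window is configurable)
across an ADP titration. The default ADP grid, 100 µM – 25 mM, brackets
the uninhibited apparent Km (~50 µM) and the inhibited one (~1.4 mM at
2.5 µM TZ). With TZ the fitted Km rises steeply (50 → 314 → 1369 µM at
0, 0.5, 2.5 µM TZ) — the competitive-inhibition signature. The fitted
maximal rate, however, rises by about 20% rather than staying fixed:
ADP cannot compete with TZ at the E·PG pocket, so the bypass persists even
at saturating ADP and genuinely raises the model's maximal turnover. A
textbook competitive inhibitor would leave Vmax untouched; this mechanism
is *not* textbook-competitive, and that deviation is part of its point.

## Configuration and outputs

`load_config()` reads YAML or JSON, accepts concentrations with units
(`"1 mM"`, `"50 nM"`) and normalises everything to µM and seconds; missing
blocks fall back to the packaged defaults
(`inst/extdata/table1_defaults.yaml`) with a notice, and unknown keys are
errors. `write_tables()` emits RFC-4180 CSVs with fixed column order and
12-significant-digit formatting — identical results produce byte-identical
files — plus a JSON manifest with package version, resolved configuration
and MD5 checksums.

## Known limitations

* The product-side and TZ dissociation constants are approximations by
  analogy; absolute production values inherit that uncertainty, which is
  why the package's checks target relative changes, occupancies and
  orderings rather than raw fluxes.
* Phosphotransfer at 5 s⁻¹ is an assumption; changing k± rescales
  quantitative activity.
* Single compartment, single protocol: no spatial effects, no stochastic
  (SSA) simulation, no fitting of rate constants to time courses, and no
  SBML exchange.
* The synthetic assay is a statistical emulation; absolute Km/Vmax values
  from the real enzyme are properties of the wet assay, not of this
  parameterisation.
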