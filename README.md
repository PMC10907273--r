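# tzpgk

Mass-action kinetics of the terazosin–PGK1 interaction: a simulation and
analysis package explaining how a competitive inhibitor can *stimulate* an
enzyme.

Phosphoglycerate kinase 1 (PGK1) catalyses the first ATP-generating step of
glycolysis — reversible phosphotransfer from 1,3-bisphosphoglycerate
(1,3-BPG) to ADP, giving 3-phosphoglycerate (3-PG) and ATP. Terazosin (TZ)
occupies PGK1's ADP/ATP pocket, yet low (nanomolar) TZ increases PGK1
activity while high (micromolar) TZ inhibits it. `tzpgk` implements the
mass-action model that resolves this paradox: TZ binding to product-bound
enzyme (E·PG) opens a bypass cycle that releases 3-PG at the fast rate
b⁻ = 160 s⁻¹ instead of the slow c⁻ = 14 s⁻¹, accelerating turnover until
outright sequestration of the enzyme takes over at high dose. It is aimed
at enzymologists and modellers studying activity modulation by active-site
ligands.

## The model

Ten enzyme configurations (E, E·ADP, E·BPG, E·ADP·BPG, E·ATP, E·PG,
E·ATP·PG, E·TZ, E·TZ·BPG, E·TZ·PG) and five free ligands are connected by
14 reversible mass-action reactions: random-order substrate and product
binding diamonds, phosphotransfer E·ADP·BPG ⇌ E·ATP·PG (k± = 5 s⁻¹), and
TZ association with the vacant nucleotide pocket at η-scaled nucleotide
on-rates (η = 562). Each interaction contributes a net flux
kf·[form][ligand] − kr·[bound form]; the ODE system is integrated with a
stiff solver under the in vitro protocol (0.04 µM PGK1, 1 mM ADP, 1,3-BPG
clamped at 80 µM, readout at 1 min).

## Worked example

```r
library(tzpgk)

net <- pgk_network()       # published rate constants, eta = 562
dose_response(net)         # 8-point terazosin grid, 60 s each
#> # A tibble: 8 × 3
#>     tz_uM atp_uM percent_change
#>     <dbl>  <dbl>          <dbl>
#> 1  0       7.91            0
#> 2  0.0025  8.11            2.52
#> 3  0.025   8.96           13.3
#> 4  0.05    9.23           16.6
#> 5  0.25    8.87           12.1
#> 6  0.5     8.04            1.56
#> 7  2.5     4.48          -43.4
#> 8 25       0.754         -90.5
```

ATP production (the total ATP pool, free plus enzyme-bound, at 60 s) rises
by ~17% at 50 nM TZ and collapses by ~90% at 25 µM — the biphasic
dose–response. Where the enzyme sits at the top dose:

```r
base <- simulate_pgk(net, sim_config(tz = 0))
high <- simulate_pgk(net, sim_config(tz = 25))
occupancy(net, high, base)
#> # A tibble: 10 × 5
#>    form      concentration_uM   fraction percent_change percent_of_enzyme
#>  1 E              0.000000166 0.00000416          -95.7             NA
#>  2 E.ADP          0.0000299   0.000747            -90.5             NA
#>  3 E.BPG          0.000170    0.00426             -90.5             NA
#>  4 E.ADP.BPG      0.00254     0.0635              -90.5             NA
#>  5 E.ATP          0.0000393   0.000982            -78.5             NA
#>  6 E.PG           0.00000212  0.0000531          -100.0             NA
#>  7 E.ATP.PG       0.0000408   0.00102             -97.4             NA
#>  8 E.TZ           0.000428    0.0107               NA                1.07
#>  9 E.TZ.BPG       0.0363      0.908                NA               90.8
#> 10 E.TZ.PG        0.000412    0.0103               NA                1.03
```

93% of the enzyme is TZ-bound, 91% in E·TZ·BPG alone: at 25 µM, TZ acts as
a straight competitive inhibitor. Other entry points:

* `net_fluxes()` / `flux_table()` — per-interaction net fluxes (the bypass
  cycle is visible at 50 nM TZ);
* `sweep_parameter("c_minus", default_cminus_grid())` +
  `classify_stimulation()` — maps the stimulation/inhibition regimes as a
  function of the c⁻/b⁻ release-rate ratio;
* `predict_apparent_km()` — the model-side competitive signature (apparent
  Km 50 → 1369 µM across 0 → 2.5 µM TZ);
* `generate_assay()` / `fit_mm()` — synthetic Michaelis–Menten assay data
  under competitive inhibition, with broom-style `tidy()`/`glance()`;
* `autoplot()` methods for dose–response, sweeps and assay fits;
* `load_config()` / `write_tables()` — YAML/JSON configs with units,
  deterministic CSV output with a checksummed run manifest.

The methods vignette (`vignettes/terazosin-pgk1-model.Rmd`) documents the
model assumptions, numerical choices and known limitations.

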