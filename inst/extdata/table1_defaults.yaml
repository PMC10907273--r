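# Default configuration: published PGK1 rate constants and the in vitro
# simulation protocol. All concentrations normalise to micromolar on read.
parameters:
  a_plus: 6.1
  a_minus: 38
  b_plus: 170
  b_minus: 160
  c_plus: 450
  c_minus: 14
  d_plus: 4.1
  d_minus: 270
  k_plus: 5.0
  k_minus: 5.0
  eta: 562
initial_conditions:
  enzyme_total: 0.04 uM
  ADP: 1 mM
  BPG: 80 uM
  ATP: 0
  PG: 0
  TZ: 0
clamped: [BPG]
tz_grid: [0, 2.5 nM, 25 nM, 50 nM, 0.25 uM, 0.5 uM, 2.5 uM, 25 uM]
simulation:
  t_end: 60
  rtol: 1.0e-9
  atol: 1.0e-12
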