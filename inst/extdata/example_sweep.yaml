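# Standard parameterization: a generated island-web-sized topology, strict
# competitive hierarchy, evenly spaced basal colonization rates, and the
# default patch-loss grid.  Usable directly with
#   Rscript inst/scripts/patchweb.R sweep --config inst/extdata/example_sweep.yaml --out sweep.csv
web:
  n_basal: 3
  n_consumers: 11
  links: 23
  seed: 7
competition:
  structure: hierarchical
rates:
  c_range: [0.45, 0.8]
  spacing: even
  e_p: 0.2
  c_a: 0.625
  e_a: 0.05
  mu: 0.05
  phi: 0.05
protocol:
  u_from: 0
  u_to: 0.95
  u_by: 0.005
  mode: full
  solver: auto
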