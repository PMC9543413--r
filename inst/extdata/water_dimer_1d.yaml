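# Reduced 1D water-dimer campaign: O-O distance RC, flat-histogram bias.
system:
  kind: water_dimer
  rc_dimension: 1
  init_orientation: antiparallel
grid:
  - {name: r, min: 2.2, max: 6.0, n_bins: 64, periodic: false}
conditions:
  temperature_K: 300
  timestep_fs: 1.0
  thermostat: nose_hoover
  tau_ps: 0.1
  n_substeps: 10
campaign:
  replicas: 16
  steps_per_replica: 20000
  iterations: 15
  flatness_threshold: 2.5
  master_seed: 1
force_field:
  boundary: periodic
  box_edge: 12
  cutoff: 14
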