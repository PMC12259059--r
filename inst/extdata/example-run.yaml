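forcefield:
  lambda_pp: 3.0
  lambda_pd: 1.0
  lambda_dd: -1.0
  epsilon: 0.20000000000000001
  k_bond: 20.0
  r0: 5.5
  k_angle: 20.0
  theta0_deg: 180.0
  cutoff_factor: 3.0
  exclude_bonded: yes
system:
  n_protein: 200
  dna_length: 50
  n_dna_chains: 4
  box_edge: 600.0
  placement: central-random
integrator:
  temperature: 300.0
  t_damp_ps: 1000.0
  dt_fs: 10.0
  n_steps: 50000
  cadence: 1000
  nve: no
analysis:
  shell_width: 10.0
  n_blocks: 5
  discard_fraction: 0.20000000000000001
  bound_threshold: 55.0
  n_interfaces: 1
  n_max_modes: 6
  residual_threshold: 0.10000000000000001
  concentration_factor: 1.0
output:
  trajectory: trajectory.rds
  xyz: ~
  log: run_log.csv
  report: report.json
seed: 1

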