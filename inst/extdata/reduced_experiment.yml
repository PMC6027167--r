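build:
  vesicle_radius: 6.5
  bilayer_thickness: 3.5
  area_per_lipid: 1.0
  n_capsaicin: 25
  n_chitosan: 5
  sequence: AGGGAGGGAGAGGGAGGGAGAGGGAGGGAGAGGGAGGGAGAGGGAGGGAG
  box_lengths:
  - 18.0
  - 18.0
  - 18.0
  length_scale: 0.646
  target_density: 3.0
params:
  gamma: 4.5
  kT: 1.0
  dt: 0.03
  lambda: 0.65
  rc: 1.0
  sigma: 3.0
bonds:
  k_spring: 100.0
  r0: 0.7
interactions:
  L1:
    L1: 25.0
    L2: 25.0
    L3: 80.0
    C1: 25.0
    C2: 45.0
    C3: 60.0
    G: 20.0
    A: 22.0
    W: 25.0
  L2:
    L1: 25.0
    L2: 25.0
    L3: 30.0
    C1: 30.0
    C2: 30.0
    C3: 40.0
    G: 30.0
    A: 30.0
    W: 45.0
  L3:
    L1: 80.0
    L2: 30.0
    L3: 25.0
    C1: 50.0
    C2: 30.0
    C3: 25.0
    G: 80.0
    A: 75.0
    W: 80.0
  C1:
    L1: 25.0
    L2: 30.0
    L3: 50.0
    C1: 25.0
    C2: 25.0
    C3: 50.0
    G: 26.0
    A: 24.0
    W: 30.0
  C2:
    L1: 45.0
    L2: 30.0
    L3: 30.0
    C1: 25.0
    C2: 25.0
    C3: 25.0
    G: 50.0
    A: 45.0
    W: 60.0
  C3:
    L1: 60.0
    L2: 40.0
    L3: 25.0
    C1: 50.0
    C2: 25.0
    C3: 25.0
    G: 80.0
    A: 75.0
    W: 80.0
  G:
    L1: 20.0
    L2: 30.0
    L3: 80.0
    C1: 26.0
    C2: 50.0
    C3: 80.0
    G: 25.0
    A: 25.0
    W: 25.0
  A:
    L1: 22.0
    L2: 30.0
    L3: 75.0
    C1: 24.0
    C2: 45.0
    C3: 75.0
    G: 25.0
    A: 23.0
    W: 28.0
  W:
    L1: 25.0
    L2: 45.0
    L3: 80.0
    C1: 30.0
    C2: 60.0
    C3: 80.0
    G: 25.0
    A: 28.0
    W: 25.0
run:
  pre_equilibration_steps: 1000
  production_steps: 100000
  snapshot_interval: 2000
  thermo_interval: 1000
  burn_in: 0.5
analysis:
  map_bin_width: 0.5
  slab_thickness: 2.0
  gr_bin_width: 0.1
  profile_bin_width: 0.25
  boundary_offset: 1.0
rng_seed: 1
output_dir: ~
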