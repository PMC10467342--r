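grid:
  L: 4.0
  n_cells: 400.0
  spacing: uniform
  ratio: 1.0
porosity:
  phi0: 0.75
  phi_inf: 0.75
  lambda: .inf
transport:
  D0:
    O2: 0.037
    NO3: 0.031
    NH4: 0.031
  w: 1.0e-05
kinetics:
  R0: 900.0
  z_att: 0.09
  r_NC: 0.150943396226415
  k_nit: 100.0
  k_amx: 0.1
  K_O2: 8.0
  K_O2nit: 4.0
  K_NO3: 15.0
  Ki_O2: 0.3
boundary:
  top:
    O2: 250.0
    NO3: 15.0
    NH4: 0.0
  bottom:
    O2: zero_gradient
    NO3: zero_gradient
    NH4: 50.0
solver:
  tol: 1.0e-10
  max_newton: 60.0
  max_halvings: 30.0
  max_ptc: 400.0
  dt0: 0.001
  verbose: no
nat:
  eps_no3: 1.0
  eps_nh4: 1.0
fit:
  free: []
  lower: []
  upper: []
  start: []
  seed: 1.0
  n_restarts: 3.0
  maxit: 500.0
synthetic:
  depths:
  - 0.05
  - 0.15
  - 0.25
  - 0.35
  - 0.45
  - 0.55
  - 0.65
  - 0.75
  - 0.85
  - 0.95
  - 1.05
  - 1.15
  - 1.25
  - 1.35
  - 1.45
  - 1.55
  - 1.65
  - 1.75
  - 1.85
  - 1.95
  - 2.05
  - 2.15
  - 2.25
  - 2.35
  - 2.45
  - 2.55
  - 2.65
  - 2.75
  - 2.85
  - 2.95
  - 3.05
  - 3.15
  - 3.25
  - 3.35
  - 3.45
  - 3.55
  - 3.65
  - 3.75
  - 3.85
  - 3.95
  noise_type: relative
  noise_sd:
    O2: 0.05
    NO3: 0.05
    NH4: 0.05
  seed: 42.0
  community:
    n_reads: 50000.0
    seed: 43.0
    niches:
    - taxon: Ca_Bathyanammoxibiaceae_like
      A: 0.074
      mu: 2.2
      sigma: 0.12
      b: 0.0
    - taxon: Ca_Subterrananammoxibiaceae_like
      A: 0.006
      mu: 2.2
      sigma: 0.08
      b: 0.0
    - taxon: Ca_Scalinduaceae_like
      A: 0.003
      mu: 2.2
      sigma: 0.15
      b: 0.0
    - taxon: background_like
      A: 0.0001
      mu: 2.0
      sigma: 1.0
      b: 0.01
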