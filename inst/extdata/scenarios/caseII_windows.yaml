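name: caseII_windows
type: case2_windows
expect:
  alt_dbar_max: 0.05
params:
  t_end: 120.0
  test_t_end: 150.0
  train_windows:
  - - 0.0
    - 45.0
  - - 20.0
    - 70.0
  steady_window: 2.0
  test_ratios:
  - 0.111111111111111
  - 9.0
config:
  name: caseII_windows
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 100000000.0
    reset_total: 10000000.0
    dilute_mediators: yes
  species:
  - id: S1
    r0: 0.5
  - id: S2
    r0: 0.3
  mediators:
  - id: C1
    kind: consumable
    C0: 0.0
    supply: 0.0
  links:
  - role: production
    mediator: C1
    species: S1
    beta: 1.0e-05
  - role: effect
    mediator: C1
    species: S2
    r: 0.4
    K: 0.5
    form: saturable
  - role: consumption
    mediator: C1
    species: S2
    alpha: 1.0e-05
    K: 1.0
    mode: monod
  init:
    S1: 5000000.0
    S2: 5000000.0
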