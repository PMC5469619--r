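name: caseI_accumulation
type: case1
expect:
  ratio_err_max: 0.01
  sat_dbar_max: 0.05
  alt_dbar_min: 0.3
params:
  t_end: 150.0
  horizon_start: 30.0
config:
  name: caseI_accumulation
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 100000000.0
    reset_total: 10000000.0
    dilute_mediators: yes
  species:
  - id: S1
    r0: 0.7
  - id: S2
    r0: 0.1
  mediators:
  - id: C1
    kind: consumable
    C0: 0.0
    supply: 0.0
  links:
  - role: production
    mediator: C1
    species: S1
    beta: 1.0e-06
  - role: effect
    mediator: C1
    species: S2
    r: 0.2
    K: 1.0
    form: saturable
  - role: consumption
    mediator: C1
    species: S2
    alpha: 1.0e-06
    K: 1.0
    mode: monod
  init:
    S1: 5000000.0
    S2: 5000000.0
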