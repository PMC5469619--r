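name: two_mediator_potency
type: two_mediator
expect:
  low_fit_dbar_max: 0.15
params:
  t_end_low: 400.0
  t_end_high: 300.0
  train_window:
  - 60.0
  - 110.0
config_low:
  name: two_mediator_potency
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 20000.0
    reset_total: 2000.0
    dilute_mediators: yes
  species:
  - id: S1
    r0: 0.5
  - id: S2
    r0: 0.4
  mediators:
  - id: C1
    kind: reusable
    C0: 0.0
    supply: 0.0
  - id: C2
    kind: reusable
    C0: 0.0
    supply: 0.0
  links:
  - role: production
    mediator: C1
    species: S1
    beta: 1.0e-06
  - role: production
    mediator: C2
    species: S1
    beta: 1.0e-06
  - role: effect
    mediator: C1
    species: S2
    r: 0.3
    K: 0.002
    form: saturable
  - role: effect
    mediator: C2
    species: S2
    r: -0.31
    K: 0.2
    form: saturable
  init:
    S1: 1000.0
    S2: 1000.0
config_high:
  name: two_mediator_potency
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 200000000.0
    reset_total: 20000000.0
    dilute_mediators: yes
  species:
  - id: S1
    r0: 0.5
  - id: S2
    r0: 0.4
  mediators:
  - id: C1
    kind: reusable
    C0: 0.0
    supply: 0.0
  - id: C2
    kind: reusable
    C0: 0.0
    supply: 0.0
  links:
  - role: production
    mediator: C1
    species: S1
    beta: 1.0e-06
  - role: production
    mediator: C2
    species: S1
    beta: 1.0e-06
  - role: effect
    mediator: C1
    species: S2
    r: 0.3
    K: 0.002
    form: saturable
  - role: effect
    mediator: C2
    species: S2
    r: -0.31
    K: 0.2
    form: saturable
  init:
    S1: 10000000.0
    S2: 10000000.0
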