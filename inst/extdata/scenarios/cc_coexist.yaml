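name: cc_coexist
type: competitive_commensal
expect:
  outcome: predicts
  dbar_test_max: 0.3
params:
  t_end: 600.0
  train_end: 150.0
config:
  name: cc_coexist
  S_ext: 0.01
  dilution:
    mode: none
    dilute_mediators: yes
  species:
  - id: S1
    r0: -0.1
  - id: S2
    r0: -0.08
  mediators:
  - id: C1
    kind: consumable
    C0: 0.0
    supply: 50.0
  - id: C2
    kind: consumable
    C0: 0.0
    supply: 0.0
  links:
  - role: effect
    mediator: C1
    species: S1
    r: 0.7
    K: 1.0
    form: saturable
  - role: consumption
    mediator: C1
    species: S1
    alpha: 1.0e-06
    mode: yield
  - role: effect
    mediator: C1
    species: S2
    r: 1.0
    K: 1.0
    form: saturable
    colimit: res
  - role: effect
    mediator: C2
    species: S2
    r: 1.0
    K: 1000.0
    form: saturable
    colimit: res
  - role: consumption
    mediator: C1
    species: S2
    alpha: 1.0e-06
    mode: yield
  - role: consumption
    mediator: C2
    species: S2
    alpha: 1.0e-06
    mode: yield
  - role: production
    mediator: C2
    species: S1
    beta: 1.0e-08
  init:
    S1: 10000000.0
    S2: 1000000.0
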