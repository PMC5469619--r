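name: chain3
type: assembly
expect:
  outcome: predicts
  dbar_max: 0.1
params:
  t_end: 250.0
  horizon_start: 20.0
config:
  name: chain3
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
    r0: 0.4
  - id: S3
    r0: 0.3
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
  - role: effect
    mediator: C1
    species: S2
    r: 0.15
    K: 6.0
    form: saturable
  - role: production
    mediator: C2
    species: S2
    beta: 1.0e-06
  - role: effect
    mediator: C2
    species: S3
    r: 0.25
    K: 0.25
    form: saturable
  init:
    S1: 3000000.0
    S2: 3000000.0
    S3: 3000000.0
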