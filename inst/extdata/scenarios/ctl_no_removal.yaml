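name: ctl_no_removal
type: assembly
expect:
  outcome: predicts
  dbar_max: 0.1
params:
  t_end: 300.0
config:
  name: ctl_no_removal
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 100000000.0
    reset_total: 10000000.0
    dilute_mediators: yes
  species:
  - id: S1
    r0: 0.45
  - id: S2
    r0: 0.3
  - id: S3
    r0: 0.35
  mediators:
  - id: C1
    kind: consumable
    C0: 0.0
    supply: 0.0
  links:
  - role: production
    mediator: C1
    species: S1
    beta: 2.0e-06
  - role: effect
    mediator: C1
    species: S2
    r: 0.3
    K: 1.0
    form: saturable
  - role: consumption
    mediator: C1
    species: S2
    alpha: 1.0e-06
    K: 1.0
    mode: monod
  init:
    S1: 3000000.0
    S2: 3000000.0
    S3: 3000000.0
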