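name: mod_share
type: assembly
expect:
  outcome: fails
  dbar_min: 0.5
params:
  t_end: 200.0
config:
  name: mod_share
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
    r0: 0.25
  - id: S3
    r0: 0.5
  mediators:
  - id: C1
    kind: reusable
    C0: 0.0
    supply: 0.0
  links:
  - role: production
    mediator: C1
    species: S1
    beta: 1.0e-06
  - role: production
    mediator: C1
    species: S3
    beta: 1.0e-06
  - role: effect
    mediator: C1
    species: S2
    r: 0.2
    K: 0.01
    form: saturable
  init:
    S1: 3000000.0
    S2: 3000000.0
    S3: 3000000.0
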