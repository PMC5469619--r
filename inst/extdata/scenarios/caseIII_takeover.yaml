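name: caseIII_takeover
type: case3
expect:
  RS_min: 1000.0
  C1_max: 0.01
  alt_dbar_max: 0.1
  verdict: S2_excludes
params:
  t_end: 120.0
config:
  name: caseIII_takeover
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 100000000.0
    reset_total: 10000000.0
    dilute_mediators: yes
  species:
  - id: S1
    r0: 0.3
  - id: S2
    r0: 0.5
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
    r: 0.3
    K: 0.5
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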