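name: density_flip
type: density_flip
expect:
  low_saturable_wins: yes
  high_alternative_wins: yes
params:
  t_end: 250.0
  horizon_start: 50.0
config_low:
  name: density_flip
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 2000000.0
    reset_total: 200000.0
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
    beta: 1.0e-06
  - role: effect
    mediator: C1
    species: S2
    r: 0.4
    K: 0.5
    form: saturable
  - role: consumption
    mediator: C1
    species: S2
    alpha: 1.0e-06
    K: 1.0
    mode: monod
  init:
    S1: 100000.0
    S2: 100000.0
config_high:
  name: density_flip
  S_ext: 0.01
  dilution:
    mode: turbidostat
    threshold: 2000000000.0
    reset_total: 200000000.0
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
    beta: 1.0e-06
  - role: effect
    mediator: C1
    species: S2
    r: 0.4
    K: 0.5
    form: saturable
  - role: consumption
    mediator: C1
    species: S2
    alpha: 1.0e-06
    K: 1.0
    mode: monod
  init:
    S1: 100000000.0
    S2: 100000000.0
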