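name: reusable_exact
type: reusable_exact
expect:
  dbar_max: 0.01
  param_rel_err_max: 0.05
params:
  t_end: 160.0
  acclimation: 40.0
  test_generations: 50.0
config:
  name: reusable_exact
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
    r: 0.3
    K: 6.0
    form: saturable
  init:
    S1: 5000000.0
    S2: 5000000.0
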