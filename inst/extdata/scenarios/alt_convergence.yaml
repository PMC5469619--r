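name: alt_convergence
type: alt_convergence
expect:
  all_agree: yes
params:
  sets:
  - label: caseII_pos_omega
    case: II
    r10: 0.5
    r20: 0.3
    rS2C1: 0.4
    omega: 0.5
    psi: 0.25
    RS0: 1.0
    expected_verdict: coexistence
  - label: caseII_neg_omega
    case: II
    r10: 0.5
    r20: 0.3
    rS2C1: 0.4
    omega: -1.0
    psi: 1.0
    RS0: 0.5
    expected_verdict: false_extinction
  - label: caseIII_pos_omega
    case: III
    r10: 0.1
    r20: 0.5
    rS2C1: 0.2
    omega: 0.8
    psi: 0.1
    RS0: 1.0
    t_end: 200.0
    expected_verdict: S1_exclusion
  - label: caseIII_neg_omega
    case: III
    r10: 0.1
    r20: 0.5
    rS2C1: 0.2
    omega: -9.0
    psi: 5.0
    RS0: 1.0
    expected_verdict: false_coexistence
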