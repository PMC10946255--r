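species:
  - id: m1
  - id: m2
  - id: m3
  - id: m4
  - id: m5
  - id: m6
  - id: m7
  - id: m8
  - id: m9
  - id: m10
  - id: s0
    boundary: true
    conc: 2.0
  - id: s10
    boundary: true
    conc: 1.0
reactions:
  - id: R0
    reactants: {s0: 1}
    products: {m1: 1}
    k_fwd: 0.0001
    k_rev: 0.0001
  - id: R1
    reactants: {m1: 1}
    products: {m2: 1}
    k_fwd: 31.622776601683793
    k_rev: 31.622776601683793
  - id: R2
    reactants: {m2: 1}
    products: {m3: 1}
    k_fwd: 10.0
    k_rev: 10.0
  - id: R3
    reactants: {m3: 1}
    products: {m4: 1}
    k_fwd: 3.1622776601683795
    k_rev: 3.1622776601683795
  - id: R4
    reactants: {m4: 1}
    products: {m5: 1}
    k_fwd: 1.0
    k_rev: 1.0
  - id: R5
    reactants: {m5: 1}
    products: {m6: 1}
    k_fwd: 0.31622776601683794
    k_rev: 0.31622776601683794
  - id: R6
    reactants: {m6: 1}
    products: {m7: 1}
    k_fwd: 0.10000000000000001
    k_rev: 0.10000000000000001
  - id: R7
    reactants: {m7: 1}
    products: {m8: 1}
    k_fwd: 0.031622776601683791
    k_rev: 0.031622776601683791
  - id: R8
    reactants: {m8: 1}
    products: {m9: 1}
    k_fwd: 0.01
    k_rev: 0.01
  - id: R9
    reactants: {m9: 1}
    products: {m10: 1}
    k_fwd: 0.0031622776601683794
    k_rev: 0.0031622776601683794
  - id: R10
    reactants: {m10: 1}
    products: {s10: 1}
    k_fwd: 5.0000000000000002e-05
    k_rev: 5.0000000000000002e-05
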