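# Two membrane compartments in the unit disk (model I).
domain:
  kind: disk2d
  D: 1.0
  gamma0: 1.0
  I0: 0.0
epsilon: 0.02
compartments:
  - centre: [0.4, 0.0]
    ell: 1.0
    kappa: 2.0
    model: I
    c0: 1.0
  - centre: [-0.4, 0.0]
    ell: 0.7
    kappa: 1.0
    model: I
    c0: 0.5
solver:
  tolerance: 1.0e-10
  order: two-term
  rho_switch: 5
  seed: 1
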