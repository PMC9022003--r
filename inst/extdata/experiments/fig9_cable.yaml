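kind: cable
stimulus:
  kind: pulse_train
  amplitude: 300.0
grid:
  dt: 0.01
  T: 300.0
n_compartments: 10.0
M0: 10000.0
seed: 42.0
id: fig9_cable
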