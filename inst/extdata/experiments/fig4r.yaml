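kind: point
model: mlif
stimulus:
  kind: pulse_train
  amplitude: -2.0
grid:
  dt: 0.01
  T: 300.0
V0: ~
orientation: -1.0
firing_polarity: negative
seed: 42.0
id: fig4r
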