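kind: point
model: mlif
stimulus:
  kind: ramp
  ramp_slope: 0.2
grid:
  dt: 0.01
  T: 100.0
V0: ~
orientation: 1.0
firing_polarity: positive
seed: 42.0
id: fig4_ramp_mlif
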