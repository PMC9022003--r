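kind: point
model: mlif
stimulus:
  kind: noise
  noise_mean: 1.5
  noise_sd: 0.5
  seed: 42.0
grid:
  dt: 0.01
  T: 500.0
V0: ~
orientation: 1.0
firing_polarity: positive
seed: 42.0
id: fig4_noise_mlif
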