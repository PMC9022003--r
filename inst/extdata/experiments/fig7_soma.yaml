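kind: point
model: mlif
stimulus:
  kind: step
  amplitude: 3.0
grid:
  dt: 0.01
  T: 600.0
soma: yes
seed: 42.0
id: fig7_soma
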