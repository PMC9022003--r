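kind: staircase
amplitude: 1.0
width: 20.0
period: 50.0
n_pulses: 5.0
dt: 0.05
seed: 42.0
id: fig3f
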