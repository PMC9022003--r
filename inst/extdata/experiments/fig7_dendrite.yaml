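kind: dendrite
dt: 0.05
T: 60.0
seed: 42.0
id: fig7_dendrite
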