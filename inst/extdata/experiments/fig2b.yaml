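kind: sweep
amplitude: 1.0
frequencies:
- 1.0
- 10.0
- 100.0
seed: 42.0
id: fig2b
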