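kind: morse
text: RO SE
seed: 42.0
id: morse_rose
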