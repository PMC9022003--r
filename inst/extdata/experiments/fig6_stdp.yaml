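kind: stdp
delta_ts:
- -10.0
- -8.0
- -6.0
- -4.0
- -2.0
- 2.0
- 4.0
- 6.0
- 8.0
- 10.0
seed: 42.0
id: fig6_stdp
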