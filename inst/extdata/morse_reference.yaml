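dt: 0.0125
M0: 10500.0
amplitude_nA: 13.0
narrow_width_ms: 0.05
wide_width_ms: 0.1
t_ss_ms: 0.02
t_s_ms: 0.04
t_l_ms: 0.1
note: reference Morse calibration; regenerate with scripts/calibrate_morse.R
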