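# quasi-static hysteresis sweep and four-phase replay
atf2_min: 0.5
atf2_max: 6.5
atf2_step: 0.25
dwell: 40
replay_levels: [3, 6, 3, 1]
phase_duration: 25
fbl_params: {}
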