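# AND-gate sign-sensitive delay and persistence detection
t_on: 12
t_off: 30
t_end: 45
epsilon: 0.05
pulse_durations: [0.6, 1.2, 2.0, 4.0, 8.0]
ffl_params: {}
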