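# leaky MITF transcript clearance under hypoxia-driven miR-155 induction
lambda: 1.0
lambda_min: 0.2
lambda_max: 2.0
n_lambda: 10
hypoxia_time: 5
t_end: 25
ffl_params: {}
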