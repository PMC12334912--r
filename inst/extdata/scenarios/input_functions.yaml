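# SOX10 -> MITF input-function comparison
sox10_max: 2.0
n_grid: 401
a: 1.0
v_max: 1.0
k_half: 0.5
hill_n: 4
boundaries: [0.25, 0.5, 0.75]
gray_width: 0.02
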