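# ATF2-activity scan of the miR-204--SOX10--ATF2 toggle switch
atf2_min: 0
atf2_max: 6
atf2_step: 0.1
irreversible_basal: 3.0
fbl_params: {}
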