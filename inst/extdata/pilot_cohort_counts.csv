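variable,count
n_total,30
females,16
current_smokers,11
copd,15
fracture_0,9
fracture_1,10
fracture_2plus,11
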