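table,outcome,method,side,U_printed
table3,stride_length,a1_vs_a2,right,31.0
table3,stride_length,a1_vs_a2,left,30.0
table6,distance,gaitup,right,25.0
table6,distance,gaitup,left,27.0
table6,distance,approach1,right,31.0
table6,distance,approach1,left,26.0
table6,distance,approach2,right,28.0
table6,distance,approach2,left,26.5
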