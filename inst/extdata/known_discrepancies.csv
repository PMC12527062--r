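table,cell,printed,oracle,note
table4,table4:P4:approach1_left,575.32,588.99,"printed insole-left stride count 387 is inconsistent; 378 reproduces the printed distance"
table4,table4:P4:approach2_left,581.36,595.21,"printed insole-left stride count 387 is inconsistent; 378 reproduces the printed distance"
table4,table4:P7:approach1_left,629.83,629.82,"half-ulp: 1.525*413 = 629.825 exactly; printed value rounds up, round-half-even rounds down"
table5,table5:P8:approach1_right,99.10,99.09,"one unit in the last digit; source presumably used unrounded distances"
table5,table5:P7:approach1_left,99.32,99.31,"one unit in the last digit; source presumably used unrounded distances"
table5,table5:P8:approach1_left,97.76,97.77,"one unit in the last digit; source presumably used unrounded distances"
table6,table6:U:approach1_right,31.0,30.0,"rank-counting oracle on the printed distances gives 30.0"
table6,table6:U:approach2_left,26.5,26.0,"rank-counting oracle on the printed distances gives 26.0"
table2,table2:all,NA,NA,"printed stride-length accuracies do not reproduce from the printed stride lengths; excluded from regression"
iqr,iqr:all,NA,NA,"printed interquartile values are internally inconsistent across tables; excluded from regression"
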