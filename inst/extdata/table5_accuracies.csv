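participant,method,side,accuracy_pct
P1,gaitup,right,97.71
P2,gaitup,right,97.14
P3,gaitup,right,97.54
P4,gaitup,right,97.17
P5,gaitup,right,98.28
P6,gaitup,right,95.98
P7,gaitup,right,99.67
P8,gaitup,right,97.61
P1,gaitup,left,98.49
P2,gaitup,left,95.85
P3,gaitup,left,99.06
P4,gaitup,left,98.43
P5,gaitup,left,98.70
P6,gaitup,left,97.07
P7,gaitup,left,97.16
P8,gaitup,left,96.57
P1,approach1,right,99.01
P2,approach1,right,99.72
P3,approach1,right,98.13
P4,approach1,right,98.61
P5,approach1,right,99.37
P6,approach1,right,96.61
P7,approach1,right,98.86
P8,approach1,right,99.10
P1,approach1,left,98.67
P2,approach1,left,97.41
P3,approach1,left,98.65
P4,approach1,left,99.93
P5,approach1,left,97.48
P6,approach1,left,99.92
P7,approach1,left,99.32
P8,approach1,left,97.76
P1,approach2,right,99.79
P2,approach2,right,98.33
P3,approach2,right,99.40
P4,approach2,right,99.21
P5,approach2,right,98.30
P6,approach2,right,98.49
P7,approach2,right,98.73
P8,approach2,right,99.47
P1,approach2,left,99.22
P2,approach2,left,94.86
P3,approach2,left,98.85
P4,approach2,left,98.88
P5,approach2,left,99.84
P6,approach2,left,99.98
P7,approach2,left,99.05
P8,approach2,left,98.89
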