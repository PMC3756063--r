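muscle,age_group,mean_rf_per_mm2,sd_rf_per_mm2
TA,1,1.96,2.04
TA,2,3.39,1.98
TA,3,4.72,2.17
TA,4,7.17,3.45
EDL,1,2.58,3.49
EDL,2,3.35,2.75
EDL,3,4.6,3.01
EDL,4,6.06,5.38
SOL,1,1.8,2.28
SOL,2,4.13,3.25
SOL,3,5.03,5.78
SOL,4,6.61,7.35
GC,1,1.13,0.96
GC,2,3.12,1.89
GC,3,4.45,2.28
GC,4,5.63,3.28
PL,1,1.56,1.8
PL,2,3.57,3.74
PL,3,5.6,4.14
PL,4,6.22,4.43
Q,1,1.09,0.54
Q,2,2.61,1.95
Q,3,3.77,2.02
Q,4,6.03,3.82
TRIC,1,1.09,1.75
TRIC,2,2.59,1.35
TRIC,3,3.72,2.23
TRIC,4,6.19,4.61
PT,1,1.48,2.09
PT,2,2.02,2.36
PT,3,2.07,1.71
PT,4,3.91,2.07
D,1,0.91,0.89
D,2,1.37,2.15
D,3,2.9,2.28
D,4,4.36,3.86
IC,1,0.98,0.84
IC,2,1.54,1.26
IC,3,2.96,3.71
IC,4,7.39,6.22
H,1,0.28,0.50
H,2,0.23,0.27
H,3,0.47,0.51
H,4,1.19,0.66
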