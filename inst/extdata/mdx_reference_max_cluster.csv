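muscle,age_group,max_cluster_size
TA,1,12
TA,2,15
TA,3,20
TA,4,24
EDL,1,8
EDL,2,7
EDL,3,8
EDL,4,11
SOL,1,4
SOL,2,20
SOL,3,14
SOL,4,29
PL,1,3
PL,2,9
PL,3,13
PL,4,22
GC,1,11
GC,2,21
GC,3,35
GC,4,26
Q,1,17
Q,2,36
Q,3,23
Q,4,30
TRIC,1,17
TRIC,2,39
TRIC,3,27
TRIC,4,60
PT,1,13
PT,2,23
PT,3,17
PT,4,17
D,1,8
D,2,21
D,3,21
D,4,19
IC,1,15
IC,2,10
IC,3,22
IC,4,58
H,1,10
H,2,8
H,3,7
H,4,11
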