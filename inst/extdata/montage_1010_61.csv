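label,x,y
Fp1,-0.307472,0.946301
Fpz,0,0.995
Fp2,0.307472,0.946301
AF3,-0.554572,0.499339
AFz,0,0.74625
AF4,0.554572,0.499339
F7,-0.804972,0.584846
F5,-0.499339,0.554572
F3,-0.473151,0.153736
F1,-0.292423,0.402486
Fz,0,0.4975
F2,0.292423,0.402486
F4,0.473151,0.153736
F6,0.499339,0.554572
F8,0.804972,0.584846
FT7,-0.946301,0.307472
FC5,-0.681733,0.303527
FC3,-0.402486,0.292423
FC1,-0.236575,0.076868
FCz,0,0.24875
FC2,0.236575,0.076868
FC4,0.402486,0.292423
FC6,0.681733,0.303527
FT8,0.946301,0.307472
T7,-0.995,0
C5,-0.74625,0
C3,-0.4975,0
C1,-0.24875,0
Cz,0,0
C2,0.24875,0
C4,0.4975,0
C6,0.74625,0
T8,0.995,0
TP7,-0.946301,-0.307472
CP5,-0.681733,-0.303527
CP3,-0.402486,-0.292423
CP1,-0.236575,-0.076868
CPz,0,-0.24875
CP2,0.236575,-0.076868
CP4,0.402486,-0.292423
CP6,0.681733,-0.303527
TP8,0.946301,-0.307472
P7,-0.804972,-0.584846
P5,-0.499339,-0.554572
P3,-0.473151,-0.153736
P1,-0.292423,-0.402486
Pz,0,-0.4975
P2,0.292423,-0.402486
P4,0.473151,-0.153736
P6,0.499339,-0.554572
P8,0.804972,-0.584846
PO7,-0.584846,-0.804972
PO5,-0.709726,-0.230604
PO3,-0.554572,-0.499339
POz,0,-0.74625
PO4,0.554572,-0.499339
PO6,0.709726,-0.230604
PO8,0.584846,-0.804972
O1,-0.307472,-0.946301
Oz,0,-0.995
O2,0.307472,-0.946301
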