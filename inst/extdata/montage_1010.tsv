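name	x	y
Fp1	-0.1437	0.9
Fpz	0	0.9
Fp2	0.1437	0.9
AF7	-0.4914	0.72
AF3	-0.2268	0.72
AFz	0	0.72
AF4	0.2268	0.72
AF8	0.4914	0.72
F7	-0.8462	0.5
F5	-0.6413	0.5
F3	-0.4275	0.5
F1	-0.2138	0.5
Fz	0	0.5
F2	0.2138	0.5
F4	0.4275	0.5
F6	0.6413	0.5
F8	0.8462	0.5
FT7	-0.9544	0.25
FC5	-0.7206	0.25
FC3	-0.4772	0.25
FC1	-0.2435	0.25
FCz	0	0.25
FC2	0.2435	0.25
FC4	0.4772	0.25
FC6	0.7206	0.25
FT8	0.9544	0.25
T7	-1	0
C5	-0.75	0
C3	-0.5	0
C1	-0.25	0
Cz	0	0
C2	0.25	0
C4	0.5	0
C6	0.75	0
T8	1	0
TP7	-0.9544	-0.25
CP5	-0.7206	-0.25
CP3	-0.4772	-0.25
CP1	-0.2435	-0.25
CPz	0	-0.25
CP2	0.2435	-0.25
CP4	0.4772	-0.25
CP6	0.7206	-0.25
TP8	0.9544	-0.25
P7	-0.8462	-0.5
P5	-0.6413	-0.5
P3	-0.4275	-0.5
P1	-0.2138	-0.5
Pz	0	-0.5
P2	0.2138	-0.5
P4	0.4275	-0.5
P6	0.6413	-0.5
P8	0.8462	-0.5
P9	-0.9517	-0.58
P10	0.9517	-0.58
PO7	-0.4914	-0.72
PO3	-0.2268	-0.72
POz	0	-0.72
PO4	0.2268	-0.72
PO8	0.4914	-0.72
O1	-0.1437	-0.9
Oz	0	-0.9
O2	0.1437	-0.9
Iz	0	-1.02
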