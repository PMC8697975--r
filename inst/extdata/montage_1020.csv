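label,x,y
Fp1,-0.247,0.761
Fpz,0.000,0.800
Fp2,0.247,0.761
F7,-0.647,0.470
F3,-0.320,0.410
Fz,0.000,0.400
F4,0.320,0.410
F8,0.647,0.470
FC5,-0.590,0.230
FC3,-0.390,0.210
FC1,-0.190,0.200
FCz,0.000,0.200
FC2,0.190,0.200
FC4,0.390,0.210
FC6,0.590,0.230
T7,-0.800,0.000
C5,-0.600,0.000
C3,-0.400,0.000
C1,-0.200,0.000
Cz,0.000,0.000
C2,0.200,0.000
C4,0.400,0.000
C6,0.600,0.000
T8,0.800,0.000
CP5,-0.590,-0.230
CP3,-0.390,-0.210
CP1,-0.190,-0.200
CPz,0.000,-0.200
CP2,0.190,-0.200
CP4,0.390,-0.210
CP6,0.590,-0.230
P7,-0.647,-0.470
P3,-0.320,-0.410
P1,-0.160,-0.400
Pz,0.000,-0.400
P2,0.160,-0.400
P4,0.320,-0.410
P8,0.647,-0.470
PO3,-0.200,-0.620
POz,0.000,-0.600
PO4,0.200,-0.620
O1,-0.247,-0.761
Oz,0.000,-0.800
O2,0.247,-0.761
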