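label	x	y
FP1	-0.2472	0.7608
FPZ	0	0.8
FP2	0.2472	0.7608
F7	-0.6472	0.4702
F3	-0.33	0.4
FZ	0	0.4
F4	0.33	0.4
F8	0.6472	0.4702
M1	-0.95	-0.25
T7	-0.8	0
C3	-0.4	0
CZ	0	0
C4	0.4	0
T8	0.8	0
M2	0.95	-0.25
P7	-0.6472	-0.4702
P3	-0.33	-0.4
PZ	0	-0.4
P4	0.33	-0.4
P8	0.6472	-0.4702
POZ	0	-0.6
O1	-0.2472	-0.7608
OZ	0	-0.8
O2	0.2472	-0.7608
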