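Cz	0.000000	0.000000	0.095000
FCz	0.000000	0.029357	0.090350
C2	0.029357	0.000000	0.090350
CPz	0.000000	-0.029357	0.090350
C1	-0.029357	-0.000000	0.090350
Fz	0.000000	0.055840	0.076857
FC2	0.039485	0.039485	0.076857
C4	0.055840	0.000000	0.076857
CP2	0.039485	-0.039485	0.076857
Pz	0.000000	-0.055840	0.076857
CP1	-0.039485	-0.039485	0.076857
C3	-0.055840	-0.000000	0.076857
FC1	-0.039485	0.039485	0.076857
AFz	0.000000	0.076857	0.055840
F2	0.029412	0.071006	0.055840
F4	0.054346	0.054346	0.055840
FC4	0.071006	0.029412	0.055840
C6	0.076857	0.000000	0.055840
CP4	0.071006	-0.029412	0.055840
P4	0.054346	-0.054346	0.055840
P2	0.029412	-0.071006	0.055840
POz	0.000000	-0.076857	0.055840
P1	-0.029412	-0.071006	0.055840
P3	-0.054346	-0.054346	0.055840
CP3	-0.071006	-0.029412	0.055840
C5	-0.076857	-0.000000	0.055840
FC3	-0.071006	0.029412	0.055840
F3	-0.054346	0.054346	0.055840
F1	-0.029412	0.071006	0.055840
Fpz	0.000000	0.090350	0.029357
AF4	0.034576	0.083473	0.029357
F6	0.063887	0.063887	0.029357
FT8	0.083473	0.034576	0.029357
T8	0.090350	0.000000	0.029357
TP8	0.083473	-0.034576	0.029357
P6	0.063887	-0.063887	0.029357
PO4	0.034576	-0.083473	0.029357
Oz	0.000000	-0.090350	0.029357
PO3	-0.034576	-0.083473	0.029357
P5	-0.063887	-0.063887	0.029357
TP7	-0.083473	-0.034576	0.029357
T7	-0.090350	-0.000000	0.029357
FT7	-0.083473	0.034576	0.029357
F5	-0.063887	0.063887	0.029357
AF3	-0.034576	0.083473	0.029357
Fp1	0.000000	0.095000	0.000000
Fp2	0.032492	0.089271	0.000000
AF7	0.061065	0.072774	0.000000
AF8	0.082272	0.047500	0.000000
F7	0.093557	0.016497	0.000000
F8	0.093557	-0.016497	0.000000
FT9	0.082272	-0.047500	0.000000
FT10	0.061065	-0.072774	0.000000
T9	0.032492	-0.089271	0.000000
T10	0.000000	-0.095000	0.000000
TP9	-0.032492	-0.089271	0.000000
TP10	-0.061065	-0.072774	0.000000
P7	-0.082272	-0.047500	0.000000
P8	-0.093557	-0.016497	0.000000
PO7	-0.093557	0.016497	0.000000
PO8	-0.082272	0.047500	0.000000
O1	-0.061065	0.072774	0.000000
O2	-0.032492	0.089271	0.000000
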