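electrode	precision_pct
Fp1	47.36
Fp2	44.73
F3	76.31
F4	63.15
C3	81.57
C4	65.78
P3	77.89
P4	69.26
O1	55.26
O2	52.63
F7	57.89
F8	57.89
T3	68.42
T4	60.52
T5	73.68
T6	60.52
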