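id,expert,acc_mask,acc3,r_opaque,r_brown
N1,Normal,94.54,92.75,0.0725,0.0000
N2,Normal,96.03,84.93,0.1507,0.0000
F1_1,Stage 1,90.05,82.18,0.1259,0.0000
F1_2,Stage 1,95.02,86.58,0.1116,0.0000
F2_1,Stage 2,78.34,62.63,0.3785,0.0000
F2_2,Stage 2,78.62,53.26,0.0920,0.0119
F3_1,Stage 3,98.40,69.64,0.3637,0.0167
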