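patient,bladder_pd_ecd,rectum_pd_ecd,bladder_pd_mdd,rectum_pd_mdd
P1,98,99,99,93
P2,100,100,100,85
P3,99,91,98,96
P4,100,85,100,56
P5,100,100,100,100
P6,95,94,79,70
P7,96,93,100,99
P8,100,89,62,91
P9,96,98,86,96
P10,98,80,100,84
P11,39,80,100,88
P12,73,97,100,53
P13,97,92,81,94
P14,96,95,97,99
P15,100,100,99,77
P16,98,96,83,99
P17,99,99,97,80
P18,89,98,99,79
P19,97,99,95,96
P20,100,99,84,60
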