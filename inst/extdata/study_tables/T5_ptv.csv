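patient,D90_ecd_pd,D90_mdd_pd,D90_mdd_ecd,D98_ecd_pd,D98_mdd_pd,D98_mdd_ecd
P1,0.3,0.2,-0.1,-2.1,-0.3,1.8
P2,-0.2,-0.3,-0.1,-1.2,-1.0,0.1
P3,-1.9,-1.7,0.2,-5.2,-4.0,1.3
P4,0.1,-0.6,-0.7,-1.0,-3.9,-3.0
P5,0.7,-0.8,-1.5,0.1,-2.5,-2.6
P6,-0.6,-0.2,0.4,-2.8,-3.0,-0.2
P7,-0.1,0.1,0.2,-0.4,0.1,0.5
P8,-1.3,-7.1,-5.8,-3.5,-23.0,-20.2
P9,-0.9,-0.1,0.9,-4.5,-2.1,2.5
P10,1.0,0.1,-0.9,1.3,-1.1,-2.3
P11,1.9,-1.2,-3.0,0.8,-2.6,-3.3
P12,0.7,-1.3,-1.9,-1.4,-4.9,-3.5
P13,0.7,-0.7,-1.4,-0.1,-2.6,-2.5
P14,-0.5,-0.9,-0.4,-1.5,-2.2,-0.7
P15,-0.2,-0.5,-0.3,-0.4,-2.8,-2.4
P16,0.7,-0.5,-1.2,-0.6,-1.5,-1.0
P17,0.2,-0.2,-0.4,-1.2,-1.5,-0.3
P18,1.3,-0.3,-1.6,1.3,-1.0,-2.3
P19,0.8,0.0,-0.8,-0.6,-0.5,0.1
P20,-0.1,-0.6,-0.5,-3.6,-3.8,-0.2
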