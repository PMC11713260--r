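patient,D2cc_ecd_pd,D2cc_mdd_pd,D2cc_mdd_ecd,Dmax_ecd_pd,Dmax_mdd_pd,Dmax_mdd_ecd,Dmean_ecd_pd,Dmean_mdd_pd,Dmean_mdd_ecd
P1,0.9,0.2,-0.7,3.5,5.1,1.6,1.2,1.6,0.4
P2,3.1,-0.6,-3.6,2.9,-1.2,-4.0,-2.1,-3.6,-1.5
P3,1.3,-0.1,-1.4,1.4,-0.1,-0.1,-2.4,-1.7,-1.7
P4,0.1,-0.7,-0.9,-5.4,-3.6,2.0,-3.3,-7.5,-4.4
P5,0.1,-0.1,-0.2,-4.2,-2.4,1.9,0.4,0.1,-0.3
P6,0.0,-0.4,-0.4,0.3,1.3,1.0,2.1,6.2,4.1
P7,-0.1,-0.2,-0.1,-0.4,-0.7,-0.3,-4.1,-1.8,2.4
P8,1.1,-0.6,-1.7,1.6,-1.0,-2.5,-1.1,-0.9,0.2
P9,1.0,0.3,-0.7,0.7,-0.5,-1.1,0.9,1.8,0.9
P10,12.4,0.2,-10.9,18.7,3.5,-12.9,5.8,0.9,-4.6
P11,2.4,-0.2,-2.5,1.0,-1.6,-2.5,-1.3,-0.3,1.1
P12,1.5,-0.5,-2.0,1.2,-0.7,-1.9,1.6,-4.2,-5.7
P13,1.8,-0.6,-2.3,1.5,-0.8,-2.3,-10.2,-10.3,-0.2
P14,-0.3,-0.6,-0.3,10.5,11.0,0.4,-2.7,-1.0,1.8
P15,1.3,-1.2,-2.4,-3.1,-9.2,-6.4,-5.5,-8.3,-2.9
P16,2.4,0.0,-2.3,2.2,-0.2,-2.4,5.0,3.7,-1.2
P17,-1.0,-1.4,-0.4,-4.6,-3.4,1.3,-7.4,-4.1,3.5
P18,7.6,0.9,-6.2,16.8,10.1,-5.7,-0.1,-1.5,-1.3
P19,3.9,-0.3,-4.0,-5.6,-0.3,5.6,3.7,-0.5,-4.1
P20,-0.5,-1.0,-0.5,-0.6,-1.0,-0.4,-15.1,-7.7,8.8
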