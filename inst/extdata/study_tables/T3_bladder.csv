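patient,D2cc_ecd_pd,D2cc_mdd_pd,D2cc_mdd_ecd,Dmax_ecd_pd,Dmax_mdd_pd,Dmax_mdd_ecd,Dmean_ecd_pd,Dmean_mdd_pd,Dmean_mdd_ecd,V45_ecd_pd,V45_mdd_pd,V45_mdd_ecd
P1,4.5,0.9,-3.6,11.3,3.2,-6.6,0.6,8.8,-0.7,129.0,123.6,-2.4
P2,4.0,-0.2,-3.9,3.1,-0.9,-4.1,4.0,9.8,-3.7,189.3,190.2,0.3
P3,1.1,0.3,-0.8,0.7,0.1,-0.6,1.1,0.2,-0.9,65.9,62.1,-2.3
P4,-4.6,-2.2,2.5,-0.9,-0.5,0.5,-0.6,-1.2,-0.7,-16.3,-21.4,-6.2
P5,0.1,-0.7,-0.6,-1.9,0.6,2.6,0.2,-0.3,-0.5,-65.5,-66.3,-2.5
P6,15.3,9.3,-5.2,7.2,5.9,-1.3,4.8,2.7,-2.1,63.5,58.6,2.4
P7,-0.1,-0.6,-0.5,4.0,-0.7,-4.5,-0.1,-0.2,-0.2,-14.3,-12.2,2.4
P8,0.3,0.2,-0.1,-0.4,-0.5,-0.1,3.2,0.6,-2.6,-24.0,-42.8,-24.7
P9,-0.2,-0.7,-0.5,-0.6,-1.2,-0.7,0.0,-0.7,-0.7,-34.5,-33.4,1.7
P10,-1.1,-2.4,-1.4,1.2,-0.4,-1.5,0.7,-0.9,-1.6,17.1,17.1,0.0
P11,2.4,-2.0,-4.3,2.6,-1.5,-4.0,2.0,-2.4,-4.3,-4.8,-81.2,-80.3
P12,1.3,-0.5,-1.8,1.1,-0.5,-1.6,6.4,3.0,-3.2,-5.7,-15.0,-9.8
P13,1.7,0.1,-1.6,1.5,-0.1,-1.6,2.8,-0.7,-3.4,-116.9,70.6,-21.4
P14,-0.2,-0.4,-0.2,-0.2,-0.8,-0.6,-13.2,-14.5,-1.6,-47.9,-52.4,-8.7
P15,3.9,3.6,-0.2,1.4,0.9,-0.5,1.6,1.2,-0.5,49.6,49.3,-0.2
P16,1.9,0.1,-1.8,1.8,0.0,-1.8,1.6,-1.4,-2.9,61.9,48.1,-8.5
P17,4.5,0.9,-3.5,13.9,11.4,-2.2,1.8,0.8,-1.0,16.3,16.3,0.0
P18,1.0,-0.5,-1.5,2.4,0.0,-2.4,3.5,1.3,-2.1,-48.2,-53.3,-9.8
P19,2.5,-0.2,-2.6,2.4,-0.3,-2.7,3.5,-0.8,-4.1,1.0,-14.3,-15.2
P20,0.7,-0.4,-1.1,0.7,-0.5,-1.1,1.0,-0.4,-1.4,-21.1,-27.7,-8.3
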