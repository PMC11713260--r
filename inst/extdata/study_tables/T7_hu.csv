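patient,image,bladder_mean,bladder_sd,muscle_mean,muscle_sd,fat_mean,fat_sd,cortical_mean,cortical_sd,trabecular_mean,trabecular_sd
P1,pCT,11.4,7.0,46.9,7.6,-97.9,15.1,851.0,158.0,143.1,46.6
P1,mCBCT,2.0,8.8,33.8,11.1,-118.1,10.8,818.7,129.7,146.8,42.7
P1,Enhanced,16.3,7.3,26.0,8.3,22.1,10.7,758.1,225.8,4.9,34.3
P3,pCT,8.4,16.0,54.5,14.8,-95.9,13.6,968.8,128.1,146.0,41.8
P3,mCBCT,3.2,12.5,15.0,9.9,-98.0,11.1,951.2,137.2,128.6,23.4
P3,Enhanced,21.0,7.8,46.8,10.5,28.1,14.8,742.2,102.4,232.3,48.0
P9,pCT,24.3,13.4,54.2,14.2,-97.4,16.3,666.2,112.0,134.2,98.2
P9,mCBCT,24.2,17.6,33.3,15.9,-96.6,7.6,614.0,164.5,101.7,60.3
P9,Enhanced,41.5,11.6,20.5,14.4,21.1,11.7,405.6,97.0,26.1,80.9
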