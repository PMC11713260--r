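patient,bladder_pct_cc,bladder_w1,bladder_w2,bladder_w3,bladder_w4,bladder_w5,bladder_median,rectum_pct_cc,rectum_w1,rectum_w2,rectum_w3,rectum_w4,rectum_w5,rectum_median
P1,89,227,217,212,-94,148,212,70,110,-98,-100,103,111,103
P2,28,288,349,107,102,104,107,90,-54,-55,-65,-51,-75,-55
P3,59,164,-73,-62,-72,137,-62,62,-91,-89,107,-92,119,-89
P4,141,-87,-109,-97,-92,-50,-92,101,-82,-98,-87,101,-84,-84
P5,149,-36,30,-34,-47,-42,-36,51,106,-86,-96,-93,-97,-93
P6,68,145,94,-93,-66,117,94,83,-60,-58,112,-69,144,-58
P7,131,-88,132,-54,-49,-37,-49,43,-95,-92,143,113,106,106
P8,48,-58,-76,-95,133,-96,-76,175,-59,-47,-58,-56,-56,-56
P9,152,-69,-57,-71,-62,-98,-69,59,123,124,-92,112,137,123
P10,41,117,110,-64,120,228,117,42,129,107,-91,106,111,107
P11,119,-43,-96,-28,-35,-73,-43,109,-77,-78,-50,-54,-76,-76
P12,80,-70,-99,-92,115,123,-70,116,-57,-63,-73,-81,101,-63
P13,83,176,163,113,199,-92,163,138,-66,-79,-67,-84,-92,-79
P14,136,-62,-39,-80,344,-88,-62,69,-97,-74,-86,102,-74,-74
P15,103,148,221,-56,139,-42,139,99,-70,123,144,-99,114,114
P16,96,159,-65,-59,-64,113,-59,75,135,166,147,176,109,147
P17,27,115,189,123,174,121,123,106,-51,-67,-59,-83,-76,-67
P18,320,-39,-46,-20,-28,-18,-28,59,-88,105,100,-93,147,100
P19,172,-89,-27,-31,-30,-33,-31,57,129,-98,123,-80,-96,-80
P20,114,-74,-69,-84,-68,-69,-69,177,-60,-67,-67,-74,-84,-67
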