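biomarker,min,max
APD20,5,120
APD50,50,250
APD90,150,350
APA,80,130
RMP,-85,-65
V20,-40,30
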