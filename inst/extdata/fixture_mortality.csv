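country_id,age,q
LOW1,40,0.02
LOW1,41,0.02
LOW1,42,0.02
LOW1,43,0.02
LOW1,44,0.02
LOW1,45,0.02
LOW1,46,0.02
LOW1,47,0.02
LOW1,48,0.02
LOW1,49,0.02
LOW1,50,0.02
LOW1,51,0.02
LOW1,52,0.02
LOW1,53,0.02
LOW1,54,0.02
LOW1,55,0.02
LOW1,56,0.02
LOW1,57,0.02
LOW1,58,0.02
LOW1,59,0.02
LOW1,60,0.02
LOW1,61,0.02
LOW1,62,0.02
LOW1,63,0.02
LOW1,64,0.02
LMC1,40,0.01
LMC1,41,0.01
LMC1,42,0.01
LMC1,43,0.01
LMC1,44,0.01
LMC1,45,0.01
LMC1,46,0.01
LMC1,47,0.01
LMC1,48,0.01
LMC1,49,0.01
LMC1,50,0.01
LMC1,51,0.01
LMC1,52,0.01
LMC1,53,0.01
LMC1,54,0.01
LMC1,55,0.01
LMC1,56,0.01
LMC1,57,0.01
LMC1,58,0.01
LMC1,59,0.01
LMC1,60,0.01
LMC1,61,0.01
LMC1,62,0.01
LMC1,63,0.01
LMC1,64,0.01
UMC1,40,0.005
UMC1,41,0.005
UMC1,42,0.005
UMC1,43,0.005
UMC1,44,0.005
UMC1,45,0.005
UMC1,46,0.005
UMC1,47,0.005
UMC1,48,0.005
UMC1,49,0.005
UMC1,50,0.005
UMC1,51,0.005
UMC1,52,0.005
UMC1,53,0.005
UMC1,54,0.005
UMC1,55,0.005
UMC1,56,0.005
UMC1,57,0.005
UMC1,58,0.005
UMC1,59,0.005
UMC1,60,0.005
UMC1,61,0.005
UMC1,62,0.005
UMC1,63,0.005
UMC1,64,0.005
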