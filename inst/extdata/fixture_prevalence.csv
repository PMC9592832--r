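country_id,income_group,age_lower,age_upper,cases,cases_lower,cases_upper
LOW1,low,40,44,100000,80000,120000
LOW1,low,60,64,50000,40000,60000
LMC1,lower_middle,40,44,400000,320000,480000
LMC1,lower_middle,60,64,200000,160000,240000
UMC1,upper_middle,40,44,300000,240000,360000
UMC1,upper_middle,60,64,150000,120000,180000
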