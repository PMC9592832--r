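country_id,gdp_per_capita,gdp_total,employment_ratio,labor_participation
LOW1,800,8000000000,0.6,0.65
LMC1,2500,100000000000,0.62,0.68
UMC1,8000,1600000000000,0.65,0.7
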