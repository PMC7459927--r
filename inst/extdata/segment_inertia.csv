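segment,centroid_position_mm,relative_position_pct,relative_mass_pct,bilateral
Neck,117.8,46.9,8.62,FALSE
Upper trunk,115.6,53.6,16.82,FALSE
Lower trunk,177.8,40.3,27.23,FALSE
Thigh,254.5,45.3,14.19,TRUE
Lower leg,224.1,39.3,3.67,TRUE
Upper arm,163.3,47.8,2.43,TRUE
Forearm,136.6,42.4,1.25,TRUE
Hand,114.2,36.6,0.64,TRUE
Foot,38.2,48.6,1.48,TRUE
Whole,734.2,43.8,NA,FALSE
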