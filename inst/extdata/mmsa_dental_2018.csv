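area_id,model_est,model_lower,model_upper,direct_est,direct_lower,direct_upper
Los Angeles-Long Beach-Anaheim,65.0,62.3,67.5,66.6,64.4,68.8
Oakland-Berkeley-Livermore,69.6,66.8,72.4,71.4,67.3,75.5
Riverside-San Bernardino-Ontario,62.8,59.7,65.7,64.8,61.7,68.0
Sacramento-Roseville-Folsom,68.3,65.7,70.8,70.9,67.1,74.8
San Jose-Sunnyvale-Santa Clara,71.0,67.7,74.3,72.9,67.9,77.9
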