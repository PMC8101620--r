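measure,reference_mean,reference_sd,ct_mean,ct_sd,pearson_r,calib_intercept,calib_slope
Tb.vBMD,505.9,78.8,1098.5,61.7,0.901,-757.679,1.150
Tb.tBMD,144.6,49.5,240.0,93.1,0.935,25.384,0.497
Tb.NA,0.72,0.30,0.62,0.30,0.924,0.145,0.931
Tb.PW,530.2,99.9,1045.7,321.6,0.913,233.730,0.284
Tb.Th,124.6,14.1,124.4,16.9,0.703,51.477,0.588
Tb.Sp,488.8,93.8,415.7,108.0,0.732,224.545,0.636
EI,0.41,0.18,0.76,0.46,0.711,0.190,0.286
SMI,0.69,0.48,1.64,1.26,0.865,0.154,0.325
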