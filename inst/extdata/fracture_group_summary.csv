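measure,mean_nofx,sd_nofx,mean_fx,sd_fx,mean_difference,pooled_sd,t_p_value,effect_size
Tb.vBMD,1135.4,48.3,1088.6,32.0,46.9,37.4,0.004,1.25
Tb.tBMD,301.0,93.6,201.0,61.4,99.9,72.1,0.002,1.39
Tb.NA,0.77,0.30,0.48,0.17,0.29,0.21,0.002,1.36
Tb.PW,1170.7,212.4,968.2,143.7,202.5,166.3,0.005,1.22
Tb.Th,126.2,14.7,116.6,6.5,9.5,9.6,0.019,0.99
Tb.Sp,331.3,79.5,499.9,187.7,-168.6,164.2,0.016,-1.03
EI,0.70,0.17,0.86,0.37,-0.16,0.33,0.232,-0.49
SMI,1.54,0.57,1.85,1.05,-0.31,0.94,0.414,-0.33
Cb.Poro,0.17,0.01,0.20,0.03,-0.03,0.03,0.022,-0.97
Cb.Th,1.64,0.60,1.56,0.59,0.08,0.59,0.738,0.13
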