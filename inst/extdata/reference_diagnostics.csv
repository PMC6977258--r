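marker,auc,youden,cutoff,sens,spec,accuracy,ppv,npv
D_SS,0.924,0.788,0.950,95.45,83.33,89.13,84.00,95.24
f_SS,0.695,0.451,0.337,90.91,54.17,71.74,64.52,86.67
D_WL,0.962,0.871,0.870,95.45,91.67,97.83,92.00,95.65
f_WL,0.756,0.530,0.353,86.36,66.67,76.09,70.37,84.21
ADC600,0.970,0.826,1.49,90.91,91.67,89.13,90.48,88.00
ADC990,0.939,0.830,1.35,95.45,87.50,91.30,87.50,95.45
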