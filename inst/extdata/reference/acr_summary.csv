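scanner_id,vendor,snr_mean,snr_sd,snr_cv_pct,iu_mean_pct,iu_sd_pct,iu_cv_pct
A,Siemens,54,1,1.8,95.1,0.5,0.6
B,Siemens,55.3,0.9,1.7,94.3,0.6,0.5
C,Siemens,52.6,1.1,2.1,88.8,4.9,5.5
D,Philips,46.8,0.9,2.0,91.7,1.3,1.7
E,Philips,48.5,4.8,9.9,94.2,0.5,2.4
F,Philips,56.5,3.3,5.8,93.6,0.5,1.4
G,GE,57,1,1.7,85.0,2.1,0.5
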