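row,volume_mean_cv,volume_sd_cv,fa_mean_cv,fa_sd_cv,md_mean_cv,md_sd_cv
inter,3.3,1.6,4.5,1.2,5.4,1.4
mean_intra,1.1,0.2,2.5,0.9,1.5,0.2
intra_A,1.3,0.8,1.9,0.7,1.2,0.5
intra_B,0.7,0.7,NA,NA,NA,NA
intra_C,1.1,1.2,1.7,1.2,1.5,1.2
intra_D,1.0,1.0,1.6,0.7,1.3,0.5
intra_E,1.2,1.0,3.7,3.2,1.8,1.7
intra_F,1.2,0.8,3.3,1.4,1.7,0.4
intra_G,1.4,0.9,2.7,1.4,1.5,0.5
vendor_Philips,1.7,0.7,4.0,2.0,2.6,0.9
vendor_Siemens,2.7,1.3,3.3,0.7,4.4,1.2
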