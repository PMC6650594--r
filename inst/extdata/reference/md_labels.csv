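label,side,inter_mean,inter_sd,inter_cv_pct,ratio,intra_mean,intra_sd,intra_cv_pct
Anterior limb internal capsule,left,7.3,0.6,8.2,5.9,7.2,0.1,1.4
Anterior limb internal capsule,right,7.4,0.6,8.1,5.8,7.3,0.1,1.4
Arcuate fasciculus region 1,left,7.2,0.4,5.6,4.0,7.2,0.1,1.4
Arcuate fasciculus region 1,right,7.3,0.4,5.5,3.9,7.3,0.1,1.4
Arcuate fasciculus region 2,left,7.5,0.3,4.0,3.1,7.5,0.1,1.3
Arcuate fasciculus region 2,right,7.3,0.2,2.7,1.9,7.3,0.1,1.4
Arcuate fasciculus region 3,left,7.5,0.3,4.0,3.1,7.5,0.1,1.3
Arcuate fasciculus region 3,right,7.6,0.3,3.9,3.0,7.6,0.1,1.3
Cingulum,left,7.6,0.4,5.3,4.1,7.6,0.1,1.3
Cingulum,right,7.5,0.4,5.3,4.1,7.5,0.1,1.3
Posterior limb internal capsule,left,7.2,0.5,6.9,4.9,7.2,0.1,1.4
Posterior limb internal capsule,right,7.0,0.4,5.7,4.1,7.0,0.1,1.4
Sagittal stratum,left,8.3,0.5,6.0,2.5,8.3,0.2,2.4
Sagittal stratum,right,8.1,0.4,4.9,4.1,8.1,0.1,1.2
Uncinate fasciculus,left,8.0,0.4,5.0,2.0,8.1,0.2,2.5
Uncinate fasciculus,right,8.1,0.3,3.7,1.5,8.1,0.2,2.5
Corpus callosum,bilateral,9.0,0.6,6.7,6.1,9.0,0.1,1.1
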