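label,side,inter_mean,inter_sd,inter_cv_pct,ratio,intra_mean,intra_sd,intra_cv_pct
Anterior limb internal capsule,left,5.1,0.2,3.9,2.0,5.1,0.1,2.0
Anterior limb internal capsule,right,5.2,0.2,3.8,1.0,5.2,0.2,3.8
Arcuate fasciculus region 1,left,4.1,0.1,2.4,1.0,4.1,0.1,2.4
Arcuate fasciculus region 1,right,4.3,0.2,4.7,2.0,4.3,0.1,2.3
Arcuate fasciculus region 2,left,3.8,0.1,2.6,1.0,3.8,0.1,2.6
Arcuate fasciculus region 2,right,4.2,0.2,4.8,2.0,4.2,0.1,2.4
Arcuate fasciculus region 3,left,4.6,0.3,6.5,3.0,4.6,0.1,2.2
Arcuate fasciculus region 3,right,4.0,0.3,7.5,1.5,4.0,0.2,5.0
Cingulum,left,4.6,0.2,4.4,2.0,4.6,0.1,2.2
Cingulum,right,4.5,0.2,4.4,2.0,4.5,0.1,2.2
Posterior limb internal capsule,left,5.8,0.2,3.4,2.0,5.8,0.1,1.7
Posterior limb internal capsule,right,5.9,0.3,5.1,3.0,5.8,0.1,1.7
Sagittal stratum,left,5.0,0.3,6.0,3.0,5.0,0.1,2.0
Sagittal stratum,right,4.6,0.2,4.4,2.0,4.6,0.1,2.2
Uncinate fasciculus,left,4.1,0.2,4.9,1.0,4.2,0.2,4.8
Uncinate fasciculus,right,3.8,0.2,5.3,1.0,3.8,0.2,5.3
Corpus callosum,bilateral,6.1,0.2,3.3,1.9,6.0,0.1,1.7
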