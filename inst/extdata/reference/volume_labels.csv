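label,side,inter_mean,inter_sd,inter_cv_pct,ratio,intra_mean,intra_sd,intra_cv_pct
Cerebellar cortex,left,51274,1258,2.5,3.1,51270,428,0.8
Cerebellar cortex,right,51490,1171,2.3,2.3,51501,521,1.0
Cingulate cortex,left,12266,324,2.6,2.2,12338,147,1.2
Cingulate cortex,right,10869,238,2.2,2.2,10919,112,1.0
Frontal cortex,left,94435,4163,4.4,3.1,94040,1306,1.4
Frontal cortex,right,96357,4384,4.6,3.3,95936,1307,1.4
Insular cortex,left,6356,106,1.7,1.9,6376,56,0.9
Insular cortex,right,6773,124,1.8,1.6,6804,72,1.1
Occipital cortex,left,33598,1015,3.0,2.5,33594,394,1.2
Occipital cortex,right,36392,1090,3.0,1.9,36295,584,1.6
Parietal cortex,left,48671,2627,5.4,3.9,48449,657,1.4
Parietal cortex,right,47279,1812,3.8,2.9,47204,631,1.3
Temporal cortex,left,61785,3102,5.0,3.3,61524,893,1.5
Temporal cortex,right,61533,3238,5.3,3.8,61207,853,1.4
Cerebellar white matter,left,18600,487,2.6,3.3,18653,144,0.8
Cerebellar white matter,right,18438,394,2.1,2.33,18491,160,0.9
Cerebral white matter,left,245773,7068,2.9,3.2,246668,2161,0.9
Cerebral white matter,right,249787,6668,2.7,3.9,250626,1745,0.7
Amygdala,left,1307,41,3.1,1.1,1309,35,2.7
Amygdala,right,1289,35,2.7,1.1,1287,32,2.5
Caudate,left,4130,195,4.7,2.9,4164,67,1.6
Caudate,right,4270,170,4.0,2.4,4305,73,1.7
Hippocampus,left,4038,65,1.6,2.7,4053,25,0.6
Hippocampus,right,3984,65,1.6,1.2,3998,50,1.3
Pallidum,left,1610,72,4.5,1.6,1622,44,2.8
Pallidum,right,1666,59,3.5,1.5,1672,37,2.3
Putamen,left,5432,222,4.1,2.4,5442,91,1.7
Putamen,right,5274,246,4.7,3.6,5299,68,1.3
Thalamus,left,7903,194,2.5,2.1,7942,95,1.2
Thalamus,right,7479,161,2.2,2.4,7517,68,0.9
Ventral diencephalon,left,5592,117,2.1,2.1,5618,57,1.0
Ventral diencephalon,right,5538,146,2.6,2.4,5564,58,1.1
Cerebellar vermal lobules I-V,bilateral,4699,148,3.2,2.1,4715,70,1.5
Cerebellar vermal lobules VI-VII,bilateral,1530,34,2.2,1.2,1529,27,1.8
Cerebellar vermal lobules VIII-X,bilateral,2938,40,1.4,1.6,2935,27,0.9
Extracerebral cerebrospinal fluid,bilateral,262844,25930,9.9,3.3,267104,8091,3.0
Intracranial cavity,bilateral,1553414,33165,2.1,4.2,1560739,7326,0.5
Ventricular cerebrospinal fluid,bilateral,19614,858,4.4,1.6,19758,527,2.7
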