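trait,kind,phase,lower,upper,env_PaulaCandido.Pulped_mean,env_PaulaCandido.Pulped_sd,env_SenhoraOliveira.Pulped_mean,env_SenhoraOliveira.Pulped_sd,env_Araponga.Pulped_mean,env_Araponga.Pulped_sd,env_Araponga.Natural_mean,env_Araponga.Natural_sd
Vigor,ordinal_score,pre_harvest,1,10,8.549,0.309,7.849,0.339,7.831,0.594,7.831,0.594
AMC,ordinal_score,pre_harvest,1,5,2.923,0.173,2.827,0.161,3.200,0.336,3.200,0.336
MU,ordinal_score,pre_harvest,1,4,2.842,0.207,3.045,0.210,2.568,0.402,2.568,0.402
FS,ordinal_score,pre_harvest,1,4,1.995,0.026,2.069,0.087,3.182,0.262,3.182,0.262
Cer,ordinal_score,pre_harvest,1,5,1.911,0.182,1.833,0.331,1.600,0.509,1.600,0.509
Rust,ordinal_score,pre_harvest,1,5,1.761,0.619,2.202,0.447,2.168,1.214,2.168,1.214
PH,continuous,pre_harvest,0,5,1.831,0.113,2.389,0.132,1.319,0.075,1.319,0.075
TopD,continuous,pre_harvest,0,5,1.316,0.085,1.431,0.086,1.173,0.064,1.173,0.064
StemD,continuous,pre_harvest,0,20,4.392,0.233,5.654,0.477,3.529,0.172,3.529,0.172
Prod,continuous,pre_harvest,0,200,66.943,15.178,21.641,6.144,57.715,8.875,57.715,8.875
DefP,percentage,post_harvest,0,100,22.000,5.273,14.364,4.306,13.818,2.620,11.500,2.818
S19,percentage,post_harvest,0,100,8.773,5.459,5.364,3.884,4.000,3.273,5.227,3.723
S18,percentage,post_harvest,0,100,16.727,5.636,14.727,6.702,16.727,7.157,16.773,6.661
S17,percentage,post_harvest,0,100,22.955,5.058,25.318,4.471,30.364,4.273,29.909,2.992
S16,percentage,post_harvest,0,100,17.091,5.934,21.727,6.050,22.727,6.273,21.636,6.066
S15,percentage,post_harvest,0,100,7.727,2.678,9.864,4.917,7.591,3.169,7.364,3.579
S14,percentage,post_harvest,0,100,4.136,0.731,3.636,1.388,3.545,1.140,3.545,1.008
MGr11,percentage,post_harvest,0,100,7.045,1.971,5.500,1.455,3.364,1.066,3.318,0.674
MGr10,percentage,post_harvest,0,100,8.136,2.124,7.227,2.037,5.273,1.529,5.636,1.182
MGr09,percentage,post_harvest,0,100,3.045,0.607,3.000,0.818,2.409,0.682,1.773,0.583
SB,percentage,post_harvest,0,100,4.364,1.033,4.091,1.281,4.000,1.091,4.833,1.000
FragAr,continuous,sensory,0,10,7.788,0.231,7.788,0.187,7.773,0.183,7.508,0.268
Taste,continuous,sensory,0,10,7.894,0.211,7.955,0.218,7.894,0.190,7.523,0.343
Acidity,continuous,sensory,0,10,7.568,0.123,7.712,0.281,7.674,0.267,7.386,0.205
Body,continuous,sensory,0,10,7.947,0.092,7.917,0.136,7.902,0.143,7.561,0.213
Aft,continuous,sensory,0,10,7.871,0.198,7.864,0.285,7.894,0.230,7.439,0.354
Balance,continuous,sensory,0,10,7.576,0.171,7.705,0.238,7.727,0.227,7.455,0.116
Overall,continuous,sensory,0,10,7.629,0.186,7.742,0.244,7.750,0.242,7.386,0.185
CleanCup,constant,sensory,0,10,10,0,10,0,10,0,10,0
Sweetness,constant,sensory,0,10,10,0,10,0,10,0,10,0
Uniformity,constant,sensory,0,10,10,0,10,0,10,0,10,0
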