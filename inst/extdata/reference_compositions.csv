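feature,wood,ref_dp,exp_low,exp_high,gen_low,gen_high
mw,spruce,20,3700,3700,3538,3722
dp,spruce,20,20,20,20,20
beta-O-4,spruce,20,12,12,12,14
beta-beta,spruce,20,1,1,1,2
beta-5,spruce,20,2,2,2,3
4-O-5,spruce,20,1,1,1,1
5-5/dbdo,spruce,20,1,1,1,1
oh_phenolic_free,spruce,20,2,2,2,4
oh_aliphatic_primary,spruce,20,11,11,11,14
oh_aliphatic_secondary,spruce,20,18,18,16,18
cinnamyl_end,spruce,20,2,2,0,1
mw,birch,18,3294,3294,3326,3570
dp,birch,18,18,18,18,18
beta-O-4,birch,18,12,12,10,13
beta-beta,birch,18,3,3,2,3
beta-5,birch,18,1,1,1,2
4-O-5,birch,18,1,1,1,2
5-5/dbdo,birch,18,0,0,0,1
oh_phenolic_free,birch,18,4,4,3,7
oh_aliphatic_primary,birch,18,NA,NA,10,13
oh_aliphatic_secondary,birch,18,13,13,11,14
cinnamyl_end,birch,18,2,2,0,2
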