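trial_id,site,crop,nutrient,rate_kg_hm2,yield_kg_hm2,yield_sd_kg_hm2
wheat_1,northern China,wheat,N,0,4133,
wheat_1,northern China,wheat,N,45,5693,
wheat_1,northern China,wheat,N,90,6458,
wheat_1,northern China,wheat,N,135,7350,
wheat_1,northern China,wheat,N,180,7178,
wheat_1,northern China,wheat,N,225,6480,
wheat_2,northern China,wheat,N,0,4313,
wheat_2,northern China,wheat,N,45,4950,
wheat_2,northern China,wheat,N,90,5063,
wheat_2,northern China,wheat,N,135,4875,
wheat_2,northern China,wheat,N,180,4688,
wheat_3,northern China,wheat,N,0,2325,
wheat_3,northern China,wheat,N,60,2700,
wheat_3,northern China,wheat,N,120,3720,
wheat_3,northern China,wheat,N,180,4260,
wheat_3,northern China,wheat,N,240,4530,
wheat_3,northern China,wheat,N,300,4343,
wheat_4,northern China,wheat,urea,0,4080,
wheat_4,northern China,wheat,urea,150,4785,
wheat_4,northern China,wheat,urea,300,5355,
wheat_4,northern China,wheat,urea,450,5783,
wheat_4,northern China,wheat,urea,600,6165,
wheat_4,northern China,wheat,urea,750,5895,
wheat_5,northern China,wheat,N,0,2177,
wheat_5,northern China,wheat,N,34,3413,
wheat_5,northern China,wheat,N,68,4112,
wheat_5,northern China,wheat,N,101,4514,
wheat_5,northern China,wheat,N,135,4716,
wheat_6,northern China,wheat,N,0,3995,
wheat_6,northern China,wheat,N,34,4355,
wheat_6,northern China,wheat,N,68,4602,
wheat_6,northern China,wheat,N,101,4658,
wheat_6,northern China,wheat,N,135,4703,
wheat_7,northern China,wheat,N,0,2453,
wheat_7,northern China,wheat,N,34,3075,
wheat_7,northern China,wheat,N,68,3585,
wheat_7,northern China,wheat,N,101,3656,
wheat_7,northern China,wheat,N,135,3615,
wheat_8,northern China,wheat,P2O5,0,2355,
wheat_8,northern China,wheat,P2O5,38,3345,
wheat_8,northern China,wheat,P2O5,75,4425,
wheat_8,northern China,wheat,P2O5,113,5078,
wheat_8,northern China,wheat,P2O5,150,5153,
wheat_8,northern China,wheat,P2O5,188,4275,
wheat_9,northern China,wheat,CS,0,480,
wheat_9,northern China,wheat,CS,300,1208,
wheat_9,northern China,wheat,CS,450,1455,
wheat_9,northern China,wheat,CS,600,1733,
wheat_9,northern China,wheat,CS,750,1995,
wheat_9,northern China,wheat,CS,900,2160,
wheat_9,northern China,wheat,CS,1125,2325,
wheat_9,northern China,wheat,CS,1500,2355,
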