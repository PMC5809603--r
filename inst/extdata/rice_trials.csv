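trial_id,site,crop,nutrient,rate_kg_hm2,yield_kg_hm2,yield_sd_kg_hm2
rice_N_datian,Datian county,rice,N,0,5051,123
rice_N_datian,Datian county,rice,N,37.5,5801,102
rice_N_datian,Datian county,rice,N,75,6483,121
rice_N_datian,Datian county,rice,N,112.5,6834,68
rice_N_datian,Datian county,rice,N,150,7001,173
rice_N_datian,Datian county,rice,N,187.5,6900,252
rice_N_datian,Datian county,rice,N,225,6675,93
rice_N_datian,Datian county,rice,N,262.5,6600,33
rice_P_nanan,Nan'an city,rice,P2O5,0,6809,286
rice_P_nanan,Nan'an city,rice,P2O5,22.5,7274,191
rice_P_nanan,Nan'an city,rice,P2O5,45,7490,180
rice_P_nanan,Nan'an city,rice,P2O5,67.5,7616,219
rice_P_nanan,Nan'an city,rice,P2O5,90,7577,344
rice_P_nanan,Nan'an city,rice,P2O5,112.5,7449,260
rice_P_nanan,Nan'an city,rice,P2O5,135,7236,180
rice_P_nanan,Nan'an city,rice,P2O5,157.5,6953,125
rice_K_datian,Datian county,rice,K2O,0,7670,87
rice_K_datian,Datian county,rice,K2O,30,8570,321
rice_K_datian,Datian county,rice,K2O,60,9215,379
rice_K_datian,Datian county,rice,K2O,90,9485,115
rice_K_datian,Datian county,rice,K2O,120,9225,189
rice_K_datian,Datian county,rice,K2O,150,8763,76
rice_K_datian,Datian county,rice,K2O,180,8411,100
rice_K_datian,Datian county,rice,K2O,210,7880,275
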