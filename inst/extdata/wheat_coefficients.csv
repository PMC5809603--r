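no,trial_id,nutrient,rate_factor,n,A,c,s0,nsfm_f,nsfm_sig,nsfm_r2,nsfm_s,b0,b1,b2,qpfm_f,qpfm_sig,qpfm_r2,qpfm_s
1,wheat_1,N,1,6,69.533,0.004788,58.298,39.6,**,0.964,294.4,4099.6,40.684,-0.1326,112.5,**,0.987,174.7
2,wheat_2,N,1,5,41.601,0.005185,104.044,44.9,*,0.978,61.3,4363.9,13.881,-0.0688,11.5,,0.920,117.6
3,wheat_3,N,1,6,21.740,0.002181,99.585,27.2,*,0.948,273.4,2149.0,16.325,-0.0288,35.1,**,0.959,242.0
4,wheat_4,urea,0.46,6,21.548,0.001864,187.08,66.5,**,0.978,150.5,4034.5,12.928,-0.0211,101.8,**,0.986,122.1
5,wheat_5,N,1,5,55.004,0.005301,39.774,2101.8,**,0.999,31.7,2212.3,38.324,-0.1482,361.1,**,0.997,76.4
6,wheat_6,N,1,5,28.639,0.003821,139.48,279.4,**,0.996,24.8,4001.0,12.052,-0.0516,170.7,**,0.994,31.7
7,wheat_7,N,1,5,41.662,0.005907,58.364,109.3,**,0.991,69.7,2443.7,23.521,-0.1105,167.1,**,0.994,56.4
8,wheat_8,P2O5,1,6,64.806,0.006027,33.830,17.7,*,0.922,388.8,2190.3,43.746,-0.1696,46.9,**,0.969,245.1
9,wheat_9,CS,0.12,8,27.635,0.004508,16.238,446.7,**,0.994,56.9,464.3,22.879,-0.0683,1582.8,**,0.998,30.3
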