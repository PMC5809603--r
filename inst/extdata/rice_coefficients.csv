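no,nutrient,n,A,c,s0,nsfm_f,nsfm_sig,nsfm_r2,nsfm_s,b0,b1,b2,qpfm_f,qpfm_sig,qpfm_r2,qpfm_s
1,N,8,47.596,0.003740,105.120,255.6,**,0.990,77.5,5087.6,22.273,-0.065,126.7,**,0.981,109.5
2,N,8,75.323,0.005517,40.359,12.8,*,0.837,577.1,3086.6,44.886,-0.145,46.4,**,0.949,323.1
3,N,8,70.609,0.005699,86.106,253.5,**,0.990,53.5,6154.7,27.199,-0.140,60.4,**,0.960,107.9
4,P2O5,8,63.739,0.005607,106.790,1189.7,**,0.998,15.9,6858.5,18.775,-0.117,138.8,**,0.982,46.1
5,P2O5,8,67.972,0.005189,112.790,23.8,**,0.905,127.7,7715.3,21.763,-0.124,21.7,**,0.897,133.1
6,P2O5,8,103.370,0.007362,71.182,64.9,**,0.963,121.9,7587.4,29.559,-0.197,14.7,**,0.855,241.0
7,K2O,8,90.851,0.005824,83.871,159.7,**,0.985,30.3,7788.7,29.707,-0.143,38.8,**,0.940,189.9
8,K2O,8,57.217,0.004921,104.670,17.0,**,0.872,179.8,6096.2,18.697,-0.083,9.6,*,0.793,228.3
9,N,6,67.582,0.004192,126.720,26.3,**,0.946,197.6,8624.6,22.802,-0.087,374.5,**,0.996,53.7
10,N,6,77.037,0.005988,63.948,16.1,*,0.915,302.6,4988.8,33.911,-0.140,255.5,**,0.994,79.2
11,N,5,51.525,0.004995,93.094,34.7,*,0.972,119.4,4825.1,21.924,-0.095,31.8,*,0.969,124.6
12,N,5,97.207,0.004710,81.760,69.4,*,0.986,214.2,8097.9,42.347,-0.1427,14.8,,0.937,452.0
13,P2O5,6,65.931,0.004634,155.330,126.3,**,0.988,26.6,10252,15.854,-0.124,280.5,**,0.995,17.9
14,K2O,7,32.950,0.004185,178.880,19.3,**,0.906,60.0,5920.3,8.1339,-0.043,11.0,*,0.846,76.9
15,K2O,7,46.920,0.003887,164.070,30.2,**,0.938,82.1,7731.3,13.863,-0.066,20.2,**,0.910,98.8
16,K2O,6,77.715,0.004429,109.860,272.3,**,0.995,68.6,8640.9,29.051,-0.111,32.7,**,0.956,194.2
17,K2O,5,39.449,0.004173,136.380,145.7,**,0.993,35.4,5394.9,13.953,-0.063,337.2,**,0.997,23.3
18,K2O,4,74.698,0.004297,135.560,396.2,*,0.999,39.8,10165.0,22.271,-0.098,15.5,,0.938,198.2
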