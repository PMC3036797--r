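patient,record_h,n_seizures,mean_seizure_s,min_seizure_s,max_seizure_s
1,18.23,17,90,17,234
2,24.74,3,370,55,669
3,24.24,149,138,10,643
4,26.10,60,63,25,106
5,24,49,354,21,1861
6,5.69,41,69,26,113
7,24.04,6,64,18,88
8,24.53,17,357,29,1154
9,24.04,156,316,16,2226
10,10.06,25,326,10,1282
11,6.19,15,326,26,469
12,12,29,131,13,384
13,12.13,25,246,71,736
14,5.48,11,514,69,1836
15,12.16,59,125,11,428
16,7.63,31,623,134,2077
17,6.64,12,512,44,1396
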