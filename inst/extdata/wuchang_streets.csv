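street_id,population,area_multi,area_low,estimated_population,fitting_error_pct,coefficient1,coefficient2
Baishazhou,78676,535235,792363.4,99206.82,-26.10,0.087527,0.040169
Huanghelou,52713,282799,307857.4,46805.24,11.21,0.124299,0.057044
Jiyuqiao,61329,495492.2,142078.4,61882.9,-0.90,0.10938,0.050198
Liangdao,64008,393565.1,458598.3,66665.45,-4.15,0.105968,0.048632
Luojiashan,62574,564579.4,228263.9,73873.29,-18.05,0.093487,0.042904
Nanhu,53159,839957.9,91927.3,97360.69,-83.14,0.060261,0.027655
Shidong,4618,11322.39,74066.45,5001.169,-8.30,0.101912,0.04677
Shouyi Road,69872,511765,225943.7,67926.76,2.78,0.113529,0.052102
Shuiguohu,172007,1397723,263553.6,167613.1,2.55,0.113261,0.051979
Xujiapeng,122129,1171513,557920.3,157556.8,-29.01,0.085551,0.039262
Yangyuan,109245,840912.3,357030.3,110893.7,-1.51,0.108727,0.049898
Zhonghua Road,44693,276456.8,370415.9,49273.92,-10.25,0.100107,0.045942
Zhongnan Road,234479,1216299,550660.3,162132,30.85,0.159617,0.073253
Ziyang,52770,253579.2,242408.3,40265.25,23.70,0.144644,0.066381
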