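frequency_hz,temperature_c,rh_pct,pressure_kpa,alpha_db_per_m
20000,0,20,101.325,0.111271
20000,0,50,101.325,0.253339
20000,0,90,101.325,0.397421
20000,10,20,101.325,0.237258
20000,10,50,101.325,0.493509
20000,10,90,101.325,0.458796
20000,20,20,101.325,0.505552
20000,20,50,101.325,0.524156
20000,20,90,101.325,0.347459
20000,30,20,101.325,0.690888
20000,30,50,101.325,0.398961
20000,30,90,101.325,0.258086
30000,0,20,101.325,0.188535
30000,0,50,101.325,0.338736
30000,0,90,101.325,0.542736
30000,10,20,101.325,0.319733
30000,10,50,101.325,0.683756
30000,10,90,101.325,0.806998
30000,20,20,101.325,0.645982
30000,20,50,101.325,0.936575
30000,20,90,101.325,0.722146
30000,30,20,101.325,1.0701
30000,30,50,101.325,0.827083
30000,30,90,101.325,0.552378
40000,0,20,101.325,0.296571
40000,0,50,101.325,0.44979
40000,0,90,101.325,0.681652
40000,10,20,101.325,0.431106
40000,10,50,101.325,0.847912
40000,10,90,101.325,1.12611
40000,20,20,101.325,0.783168
40000,20,50,101.325,1.31824
40000,20,90,101.325,1.17255
40000,30,20,101.325,1.36909
40000,30,50,101.325,1.34047
40000,30,90,101.325,0.947177
60000,0,20,101.325,0.605152
60000,0,50,101.325,0.760584
60000,0,90,101.325,1.01536
60000,10,20,101.325,0.746281
60000,10,50,101.325,1.20794
60000,10,90,101.325,1.69388
60000,20,20,101.325,1.12252
60000,20,50,101.325,1.97996
60000,20,90,101.325,2.15848
60000,30,20,101.325,1.87974
60000,30,50,101.325,2.45608
60000,30,90,101.325,1.98018
80000,0,20,101.325,1.03713
80000,0,50,101.325,1.19335
80000,0,90,101.325,1.45684
80000,10,20,101.325,1.18645
80000,10,50,101.325,1.66552
80000,10,90,101.325,2.26123
80000,20,20,101.325,1.57727
80000,20,50,101.325,2.60604
80000,20,90,101.325,3.1487
80000,30,20,101.325,2.41542
80000,30,50,101.325,3.55907
80000,30,90,101.325,3.24071
90000,0,20,101.325,1.2994
90000,0,50,101.325,1.45583
90000,0,90,101.325,1.72174
90000,10,20,101.325,1.45357
90000,10,50,101.325,1.93751
90000,10,90,101.325,2.56778
90000,20,20,101.325,1.85096
90000,20,50,101.325,2.934
90000,20,90,101.325,3.63739
90000,30,20,101.325,2.71521
90000,30,50,101.325,4.09541
90000,30,90,101.325,3.9255
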