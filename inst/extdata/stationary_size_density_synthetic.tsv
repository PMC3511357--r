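# Synthetic stationary normalized-size density at the reference hESC parameters.
# Produced by the package itself: stationarySizeDistribution(hescParams()),
# finite-difference solution of the size-structured population balance equation
# (400 cells on [0, 1.2], hybrid leapfrog/Lax-Friedrichs advection, exact
# division sink, beta-kernel birth quadrature). No experimental data.
x	density
0.0015	4.795772e-06
0.0045	0
0.0075	2.6843046e-06
0.0105	1.4222408e-08
0.0135	1.4852064e-06
0.0165	2.6610111e-07
0.0195	9.054043e-07
0.0225	3.6310239e-07
0.0255	6.2357821e-07
0.0285	3.8246186e-07
0.0315	5.1086129e-07
0.0345	5.0879924e-07
0.0375	9.2760268e-07
0.0405	1.97718e-06
0.0435	4.8332405e-06
0.0465	1.1440581e-05
0.0495	2.5712975e-05
0.0525	5.431709e-05
0.0555	0.00010836019
0.0585	0.00020517563
0.0615	0.0003707866
0.0645	0.0006426323
0.0675	0.001072747
0.0705	0.0017310923
0.0735	0.0027090039
0.0765	0.0041224671
0.0795	0.0061150572
0.0825	0.0088602709
0.0855	0.012563054
0.0885	0.017460315
0.0915	0.023820282
0.0945	0.031940616
0.0975	0.042145256
0.1005	0.054780047
0.1035	0.070207266
0.1065	0.088799228
0.1095	0.11093118
0.1125	0.13697376
0.1155	0.16728524
0.1185	0.2022039
0.1215	0.24204065
0.1245	0.28707226
0.1275	0.33753528
0.1305	0.3936208
0.1335	0.4554702
0.1365	0.52317186
0.1395	0.5967589
0.1425	0.67620791
0.1455	0.76143867
0.1485	0.85231467
0.1515	0.94864452
0.1545	1.050184
0.1575	1.1566389
0.1605	1.2676681
0.1635	1.3828875
0.1665	1.501874
0.1695	1.62417
0.1725	1.7492879
0.1755	1.8767153
0.1785	2.0059197
0.1815	2.1363533
0.1845	2.2674586
0.1875	2.398673
0.1905	2.529434
0.1935	2.6591837
0.1965	2.7873736
0.1995	2.9134692
0.2025	3.0369537
0.2055	3.1573323
0.2085	3.2741357
0.2115	3.3869229
0.2145	3.4952844
0.2175	3.5988445
0.2205	3.6972633
0.2235	3.7902379
0.2265	3.8775041
0.2295	3.9588367
0.2325	4.0340497
0.2355	4.1029966
0.2385	4.1655694
0.2415	4.2216981
0.2445	4.2713493
0.2475	4.3145245
0.2505	4.3512591
0.2535	4.3816193
0.2565	4.4057011
0.2595	4.4236268
0.2625	4.4355437
0.2655	4.4416208
0.2685	4.4420464
0.2715	4.4370258
0.2745	4.4267786
0.2775	4.4115361
0.2805	4.3915391
0.2835	4.3670356
0.2865	4.3382782
0.2895	4.3055227
0.2925	4.2690254
0.2955	4.2290423
0.2985	4.1858264
0.3015	4.1396272
0.3045	4.0906889
0.3075	4.0392495
0.3105	3.9855395
0.3135	3.9297816
0.3165	3.8721899
0.3195	3.812969
0.3225	3.7523142
0.3255	3.6904107
0.3285	3.6274339
0.3315	3.5635491
0.3345	3.4989114
0.3375	3.4336664
0.3405	3.3679496
0.3435	3.3018874
0.3465	3.2355968
0.3495	3.1691862
0.3525	3.1027555
0.3555	3.0363966
0.3585	2.9701938
0.3615	2.9042243
0.3645	2.8385585
0.3675	2.7732605
0.3705	2.7083887
0.3735	2.6439959
0.3765	2.58013
0.3795	2.5168342
0.3825	2.4541476
0.3855	2.3921053
0.3885	2.330739
0.3915	2.2700771
0.3945	2.2101451
0.3975	2.150966
0.4005	2.0925603
0.4035	2.0349465
0.4065	1.978141
0.4095	1.9221587
0.4125	1.8670128
0.4155	1.8127153
0.4185	1.7592767
0.4215	1.7067066
0.4245	1.6550134
0.4275	1.6042047
0.4305	1.5542873
0.4335	1.5052669
0.4365	1.457149
0.4395	1.4099379
0.4425	1.3636374
0.4455	1.318251
0.4485	1.2737811
0.4515	1.2302298
0.4545	1.1875987
0.4575	1.1458885
0.4605	1.1050997
0.4635	1.0652321
0.4665	1.0262847
0.4695	0.98825622
0.4725	0.95114471
0.4755	0.91494759
0.4785	0.87966172
0.4815	0.84528335
0.4845	0.81180812
0.4875	0.77923109
0.4905	0.74754668
0.4935	0.71674871
0.4965	0.6868304
0.4995	0.65778436
0.5025	0.62960259
0.5055	0.60227649
0.5085	0.5757969
0.5115	0.55015407
0.5145	0.52533767
0.5175	0.50133685
0.5205	0.47814021
0.5235	0.45573585
0.5265	0.43411137
0.5295	0.4132539
0.5325	0.39315014
0.5355	0.37378634
0.5385	0.35514839
0.5415	0.33722178
0.5445	0.3199917
0.5475	0.30344299
0.5505	0.28756025
0.5535	0.2723278
0.5565	0.25772978
0.5595	0.24375012
0.5625	0.23037261
0.5655	0.2175809
0.5685	0.20535859
0.5715	0.19368918
0.5745	0.18255616
0.5775	0.17194304
0.5805	0.16183333
0.5835	0.15221063
0.5865	0.14305861
0.5895	0.13436106
0.5925	0.12610191
0.5955	0.11826526
0.5985	0.11083539
0.6015	0.1037968
0.6045	0.097134221
0.6075	0.090832623
0.6105	0.084877255
0.6135	0.079253646
0.6165	0.073947626
0.6195	0.068945338
0.6225	0.064233252
0.6255	0.059798172
0.6285	0.05562725
0.6315	0.05170799
0.6345	0.048028256
0.6375	0.044576279
0.6405	0.04134066
0.6435	0.038310371
0.6465	0.035474759
0.6495	0.032823547
0.6525	0.030346829
0.6555	0.028035076
0.6585	0.025879126
0.6615	0.023870185
0.6645	0.02199982
0.6675	0.020259959
0.6705	0.018642879
0.6735	0.017141202
0.6765	0.01574789
0.6795	0.014456236
0.6825	0.013259856
0.6855	0.01215268
0.6885	0.011128943
0.6915	0.01018318
0.6945	0.0093102118
0.6975	0.008505137
0.7005	0.007763324
0.7035	0.0070803996
0.7065	0.0064522403
0.7095	0.0058749618
0.7125	0.0053449095
0.7155	0.0048586489
0.7185	0.0044129562
0.7215	0.0040048082
0.7245	0.0036313735
0.7275	0.0032900031
0.7305	0.0029782214
0.7335	0.0026937176
0.7365	0.0024343367
0.7395	0.0021980718
0.7425	0.0019830555
0.7455	0.0017875524
0.7485	0.0016099513
0.7515	0.0014487581
0.7545	0.0013025889
0.7575	0.0011701631
0.7605	0.0010502969
0.7635	0.00094189743
0.7665	0.00084395673
0.7695	0.00075554609
0.7725	0.00067581081
0.7755	0.00060396518
0.7785	0.00053928763
0.7815	0.00048111622
0.7845	0.0004288444
0.7875	0.00038191691
0.7905	0.00033982604
0.7935	0.00030210802
0.7965	0.00026833969
0.7995	0.00023813535
0.8025	0.0002111438
0.8055	0.00018704562
0.8085	0.0001655506
0.8115	0.00014639532
0.8145	0.00012934096
0.8175	0.00011417123
0.8205	0.00010069045
0.8235	8.8721742e-05
0.8265	7.8105447e-05
0.8295	6.869756e-05
0.8325	6.0368347e-05
0.8355	5.3001055e-05
0.8385	4.6490717e-05
0.8415	4.0743071e-05
0.8445	3.567355e-05
0.8475	3.1206367e-05
0.8505	2.7273677e-05
0.8535	2.3814805e-05
0.8565	2.077555e-05
0.8595	1.8107539e-05
0.8625	1.5767652e-05
0.8655	1.3717489e-05
0.8685	1.1922888e-05
0.8715	1.0353492e-05
0.8745	8.9823527e-06
0.8775	7.7855707e-06
0.8805	6.7419762e-06
0.8835	5.8328347e-06
0.8865	5.0415853e-06
0.8895	4.3536031e-06
0.8925	3.7559874e-06
0.8955	3.2373695e-06
0.8985	2.787742e-06
0.9015	2.3983045e-06
0.9045	2.0613267e-06
0.9075	1.7700248e-06
0.9105	1.5184525e-06
0.9135	1.3014027e-06
0.9165	1.1143205e-06
0.9195	9.5322576e-07
0.9225	8.1464413e-07
0.9255	6.9554608e-07
0.9285	5.9329269e-07
0.9315	5.055877e-07
0.9345	4.3043513e-07
0.9375	3.6610185e-07
0.9405	3.1108455e-07
0.9435	2.6408064e-07
0.9465	2.2396264e-07
0.9495	1.8975568e-07
0.9525	1.6061774e-07
0.9555	1.3582227e-07
0.9585	1.147431e-07
0.9615	9.6841057e-08
0.9645	8.1652437e-08
0.9675	6.8778825e-08
0.9705	5.787828e-08
0.9735	4.865764e-08
0.9765	4.0865829e-08
0.9795	3.4288046e-08
0.9825	2.8740716e-08
0.9855	2.4067122e-08
0.9885	2.0133615e-08
0.9915	1.682634e-08
0.9945	1.4048409e-08
0.9975	1.1717461e-08
1.0005	9.7635572e-09
1.0035	8.1273708e-09
1.0065	6.7586323e-09
1.0095	5.6147908e-09
1.0125	4.6598684e-09
1.0155	3.8634768e-09
1.0185	3.1999769e-09
1.0215	2.6477594e-09
1.0245	2.1886314e-09
1.0275	1.8072924e-09
1.0305	1.4908887e-09
1.0335	1.2286332e-09
1.0365	1.0114836e-09
1.0395	8.3186758e-10
1.0425	6.8345139e-10
1.0455	5.6094258e-10
1.0485	4.599237e-10
1.0515	3.7671164e-10
1.0545	3.0823889e-10
1.0575	2.519534e-10
1.0605	2.0573428e-10
1.0635	1.678209e-10
1.0665	1.3675323e-10
1.0695	1.1132189e-10
1.0725	9.052619e-11
1.0755	7.3539024e-11
1.0785	5.9677508e-11
1.0815	4.8378449e-11
1.0845	3.9177876e-11
1.0875	3.1693981e-11
1.0905	2.5612907e-11
1.0935	2.0676945e-11
1.0965	1.667472e-11
1.0995	1.343305e-11
1.1025	1.0810203e-11
1.1055	8.6903139e-12
1.1085	6.9787666e-12
1.1115	5.5983848e-12
1.1145	4.4862849e-12
1.1175	3.5912889e-12
1.1205	2.8717868e-12
1.1235	2.293993e-12
1.1265	1.8304945e-12
1.1295	1.4590894e-12
1.1325	1.1617938e-12
1.1355	9.2408944e-13
1.1385	7.3422125e-13
1.1415	5.8275184e-13
1.1445	4.6201162e-13
1.1475	3.6592318e-13
1.1505	2.8946132e-13
1.1535	2.2879422e-13
1.1565	1.8055045e-13
1.1595	1.4246472e-13
1.1625	1.120851e-13
1.1655	8.8388623e-14
1.1685	6.9183232e-14
1.1715	5.4742656e-14
1.1745	4.231283e-14
1.1775	3.4088621e-14
1.1805	2.5389141e-14
1.1835	2.2002223e-14
1.1865	1.4451849e-14
1.1895	1.6060792e-14
1.1925	6.438726e-15
1.1955	1.3151048e-14
1.1985	0
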