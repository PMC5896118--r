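mean	dispersion
14.877749530	0.41587163884
688.083282952	2.20986049445
93.998059205	0.11105654006
123.593567187	4.97731353276
50.891804209	0.57604693594
193.153801461	0.17538754538
113.904204760	0.17236308865
84.644072960	0.17338513049
282.252436344	3.62259140352
131.575029283	0.78282002538
41.212947607	0.09294107496
204.610128918	0.13585150014
56.312805743	4.20351093154
90.454190912	2.27843402073
45.454771544	0.14194798070
30.987147563	0.87846043402
53.475869532	0.28790501105
163.253114668	0.37135780928
37.834136917	0.07633039265
23.773831714	2.04241620392
9.378050241	0.20920602041
235.034918415	0.83656467318
66.398347194	0.28131869234
113.958800035	0.11874740573
26.267488533	1.20773905568
245.192905008	0.11365486285
674.085506789	1.40940502176
443.048132020	0.62043757033
27.697184867	0.13703178723
13.000840692	1.92459808159
131.013705200	0.07384712537
62.197932258	0.44157877081
271.382701133	0.92264296662
144.130549456	0.47360718593
29.831212492	1.28575748876
186.929499355	1.06896159889
107.617610724	0.10179002943
246.608932514	2.12051401769
34.095035157	4.20764282890
360.921700493	0.18077994538
300.001695010	0.52909955361
208.319875943	0.11687020824
113.124255934	1.09968587460
45.054974488	0.43616839105
54.360000841	0.05083863081
178.856361893	0.78839335254
99.191180926	0.21294605800
3.930131089	0.20627251693
79.148028787	1.82878098181
24.557621349	1.12886030501
21.636002202	0.11255319762
108.913628408	3.68385141689
23.960592911	0.15810754817
66.818650609	0.05433639302
63.698755869	1.83729594671
236.342623798	0.12324104566
53.360244239	0.20910014006
42.671383310	0.09043039903
20.951595133	1.14735792478
51.970946080	3.12136469081
78.437007996	0.13420165118
275.364649033	0.05259553518
404.885445805	0.07747647101
153.012570127	0.08468074642
44.808293126	0.12549995258
52.342313683	0.55221317611
159.397305116	0.62182037447
31.418482044	0.23020637406
66.331738266	1.35897709349
50.891529220	0.29007452336
97.864965374	0.19831265946
135.372027081	3.28259335402
322.908097204	2.78414509193
99.482689752	0.84184848543
104.493723787	0.13491911490
28.938854260	0.81009292485
111.734034809	0.80444662198
78.387540542	2.92900860154
2.575607861	3.92435495183
44.093902472	0.46678181498
127.132929168	0.93121624926
20.186567074	0.88038489483
119.624367988	0.28247302162
518.770367174	0.24951823848
330.090890651	0.14262220130
15.779080047	0.36643212130
244.818175133	0.05157443345
558.259734178	0.40599942592
1414.364833759	2.04721659436
146.647941363	0.18381401905
100.910287816	1.47419861572
99.461109499	0.42140336160
52.786412526	4.90460659888
40.659346299	1.04554112953
396.226691423	0.28608555766
10.263779417	0.56955007819
127.628228560	0.63788784795
30.596683535	1.17176260662
17.282610010	3.11082532076
69.345353930	0.21965039035
380.378825149	0.48920847199
497.753664643	2.67833807190
155.603752632	0.45472075640
19.379698831	0.17388350109
8.246295911	2.95792542669
14.202148324	0.07766463917
1768.623460217	2.33999325175
201.968496489	0.09521747491
284.124058879	0.14244831613
19.544766439	1.12615117555
27.085979096	0.24554336070
667.666362273	0.05722196779
5.483558029	0.24477221621
115.868694832	3.60757355385
226.208468687	0.08162152063
118.268532614	1.64394985498
102.139887649	1.31310181173
910.112461502	1.26178761512
93.145566490	0.65749239568
149.681729245	0.31880745862
165.784596511	3.31961896331
190.207148308	3.89985443125
40.542531339	2.90503915502
50.829292545	0.06637644917
51.057413300	1.83239642161
1087.528676783	0.50040153936
36.470405048	1.88538180393
242.360771888	3.05599744765
159.756877737	0.44719187125
16.734572521	0.13709830220
211.950321407	0.15603617114
232.206196525	0.24006215455
1620.421427194	0.05969002487
44.281479966	1.60961334548
69.289162800	0.69633995530
58.312638218	0.06731350617
845.184852627	0.08079383909
208.779795624	2.29771553783
45.757847759	0.47473139190
85.222670582	2.57862815242
55.769932558	0.27952102899
87.933787179	0.14438299975
89.929720948	0.05354908405
160.497949406	0.90679295978
68.240646566	0.48089608634
249.391086317	0.07907462060
160.272684756	1.00067215768
60.477548521	3.23687479584
21.462556109	1.30053248366
15.836243111	0.39059319380
45.644935579	2.83557380498
470.219153606	0.09880788782
147.503404578	1.28195126319
205.669987158	0.15700997788
45.648456883	2.56033523347
307.290779101	4.80059706806
711.907093728	0.05102266629
233.248250648	2.26013258612
83.818389313	0.05034218177
94.962068885	0.48049049328
116.951294446	0.08515648476
32.620423073	3.17838973302
443.535665518	0.61534664983
261.955113722	0.36996041651
115.972174615	0.96837107846
218.342658404	1.94511483395
30.788801919	0.11993308490
68.397860578	3.08737965844
87.865058123	2.52787546793
51.038251511	0.61790343165
111.236974669	3.06594370948
12.123196274	0.32174933369
34.641038058	0.18823734672
37.922591133	0.10219581458
2.995076417	1.05364603245
40.379608208	2.47489398331
112.936628732	0.05372752436
121.497911976	0.08449083421
147.367064562	1.16868708523
117.977690521	0.39271540882
51.540906397	0.33757163464
38.855626510	0.37386383534
37.884103046	0.29651693802
162.414880407	0.26902352691
119.037189512	4.52106901135
299.336770759	0.19502735583
221.208628728	0.28269384014
18.682920492	0.68649910527
100.346069885	0.27450135178
111.200271166	0.21116376101
147.910591708	2.60121619498
33.133402530	0.16055159655
55.903133313	0.09617044020
378.857637847	4.43060542170
191.010636733	3.49431141462
47.775441091	4.94292575766
35.397281341	1.06440055409
83.489517580	0.53980917151
195.642731284	0.50885092852
44.919639241	0.16187276633
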