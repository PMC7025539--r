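chr	female_markers	female_cM	female_bins	male_markers	male_cM	male_bins
1	268	232.874	98	522	165.979	95
2	355	216.454	101	341	169.818	82
3	308	207.305	91	312	127.713	63
4	222	221.467	72	377	117.929	65
5	262	179.227	81	387	89.749	52
6	378	333.996	120	773	192.604	100
7	304	229.924	113	487	143.868	85
8	291	207.785	99	263	133.481	53
9	225	198.075	75	317	166.185	72
10	527	474.952	187	715	283.975	148
11	402	443.421	160	607	196.433	113
12	382	263.992	119	484	210.657	101
13	298	252.841	97	443	186.844	82
14	262	260.901	88	379	112.722	62
15	369	241.160	113	632	140.747	96
16	264	205.234	89	199	127.797	54
17	294	233.648	95	369	129.562	65
18	357	188.878	97	424	169.573	85
19	340	290.418	112	404	196.065	91
20	182	154.145	63	337	127.779	65
21	205	186.505	71	289	95.021	50
22	286	231.551	90	364	151.210	77
23	225	225.217	80	312	102.030	73
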