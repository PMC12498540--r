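# Group-mean methylation index (MI) for WT ESC/NSC/neuron, with one-way ANOVA
# and Tukey MCT p-values per site. p-values below print precision are stored as 1e-04.
molecule_id	position	mi_esc	mi_nsc	mi_neuron	anova_p	tukey_esc_nsc	tukey_esc_neuron	tukey_nsc_neuron
18S	27	0.993126	0.993779	1.0	0.429	0.993	0.492	0.507
18S	99	0.964139	0.994675	0.9924365	0.00293	0.0038	0.006	0.927
18S	116	0.886409	0.913716	0.9727528	0.0001	0.0511	0.0001	0.0004
18S	121	0.975219	0.992299	0.9968943	0.00215	0.0084	0.002	0.488
18S	159	0.983293	0.975395	0.9979098	0.0001	0.0512	0.002	0.0001
18S	166	0.991444	0.990237	0.9942913	0.194	0.853	0.443	0.181
18S	172	0.773057	0.986251	0.9861445	0.0001	0.0001	0.0001	0.999
18S	174	0.62519	0.891424	0.957827	0.000161	0.0007	0.0002	0.282
18S	428	0.338442	0.762446	0.959955	0.0001	0.0001	0.0001	0.0001
18S	436	0.932921	0.726662	0.9383833	0.000694	0.0021	0.99	0.0011
18S	462	0.977988	0.995158	0.9960748	0.00913	0.016	0.0122	0.976
18S	468	0.909771	0.994058	0.9978048	0.0013	0.0025	0.0019	0.968
18S	484	0.922278	0.984663	0.991567	0.000655	0.0016	0.0008	0.799
18S	509	0.967931	0.992193	0.9920413	0.00128	0.0021	0.0022	0.999
18S	512	0.964674	0.978501	0.9877608	0.0023	0.0304	0.0018	0.111
18S	517	0.985335	0.994519	0.9905125	0.169	0.148	0.49	0.599
18S	576	0.881844	0.758204	0.8967893	0.0301	0.0777	0.949	0.0352
18S	590	0.977527	0.998987	0.9992265	0.000178	0.0003	0.0003	0.996
18S	601	0.976304	0.998684	0.997167	0.00554	0.0072	0.0106	0.949
18S	627	0.885702	0.984896	0.9938585	0.0001	0.0001	0.0001	0.624
18S	644	0.985892	0.99891	0.9967683	0.000132	0.0001	0.0005	0.395
18S	668	0.902507	0.972097	0.9391228	0.00969	0.0077	0.131	0.143
18S	683	0.994139	0.999611	0.9982948	0.0702	0.0652	0.166	0.773
18S	797	0.960798	0.975845	0.9908723	0.00207	0.0624	0.0016	0.0456
18S	799	0.977258	0.991295	0.973921	0.312	0.501	0.958	0.314
18S	867	0.723714	0.978765	0.9940543	0.0001	0.0001	0.0001	0.677
18S	1031	0.983998	0.996362	0.9975953	0.0001	0.0001	0.0001	0.565
18S	1272	0.450539	0.40198	0.8331725	0.0001	0.162	0.0001	0.0001
18S	1288	0.954468	0.982487	0.9679955	0.0355	0.0298	0.32	0.232
18S	1326	0.974528	0.985004	0.9950905	0.0538	0.345	0.0452	0.32
18S	1328	0.974711	0.886104	0.5649975	0.108	0.881	0.124	0.202
18S	1383	0.994346	0.998894	0.9972805	0.000857	0.0007	0.0098	0.102
18S	1391	0.998099	0.989368	0.9447543	0.000101	0.463	0.0002	0.0003
18S	1442	0.935299	0.994245	0.975143	0.0001	0.0001	0.0002	0.0133
18S	1447	0.600625	0.0	0.8380905	0.0001	0.0001	0.0009	0.0001
18S	1490	0.999182	0.99947	0.9994388	0.366	0.381	0.457	0.985
18S	1536	0.938834	0.225773	0.254877	0.0001	0.0001	0.0001	0.914
18S	1602	0.026374	0.0397198	0.591	0.802	0.944	0.57	1.0
18S	1668	0.012691	0.0212655	0.586	0.83	0.918	0.56	1.0
18S	1678	0.970023	0.997875	0.993371	0.00369	0.0039	0.0106	0.701
18S	1703	0.987796	0.997955	0.9969368	0.0273	0.0315	0.0501	0.938
18S	1804	0.915503	0.99427	0.9967138	0.0001	0.0001	0.0001	0.665
28S	398	0.998006	0.997673	0.993328	0.0662	0.984	0.101	0.0997
28S	400	0.995383	0.983287	0.993876	0.000101	0.0002	0.64	0.0003
28S	1316	0.825662	0.747368	0.964756	0.000114	0.0585	0.0031	0.0001
28S	1326	0.972769	0.988575	0.984236	0.0138	0.0121	0.0551	0.517
28S	1340	0.873736	0.00154	0.868292	0.0001	0.0001	0.971	0.0001
28S	1522	0.663124	0.994978	0.991648	0.000406	0.0007	0.0007	0.998
28S	1524	0.933567	0.99479	0.995877	0.0001	0.0001	0.0001	0.938
28S	1534	0.998708	0.997734	0.999203	0.136	0.397	0.771	0.123
28S	1625	0.988571	0.998125	0.993423	0.0284	0.0234	0.258	0.231
28S	1760	0.898756	0.996909	0.997488	0.0001	0.0001	0.0001	0.989
28S	1871	0.995832	0.996764	0.999337	0.15	0.85	0.159	0.285
28S	1881	0.515724	0.603932	0.933649	0.0001	0.0547	0.0001	0.0001
28S	2351	0.960067	0.98108	0.992865	0.00011	0.0018	0.0001	0.0287
28S	2363	0.969565	0.997901	0.994424	0.0001	0.0001	0.0001	0.405
28S	2364	0.989246	0.996409	0.99011	0.000843	0.0015	0.792	0.0021
28S	2365	0.871694	0.961157	0.975329	0.00341	0.0089	0.0038	0.772
28S	2401	0.983286	0.85977	0.98724	0.0001	0.0001	0.842	0.0001
28S	2415	0.791581	0.918155	0.952379	0.0001	0.0001	0.0001	0.0003
28S	2422	0.911944	0.975664	0.984815	0.0001	0.0001	0.0001	0.371
28S	2424	0.968366	0.98321	0.988908	0.0001	0.0003	0.0001	0.0429
28S	2787	0.886671	0.858685	0.894799	0.35	0.558	0.949	0.345
28S	2804	0.92773	0.95782	0.986964	0.000156	0.0093	0.0001	0.0072
28S	2815	0.978796	0.993602	0.996322	0.000541	0.0018	0.0006	0.563
28S	2824	0.545519	0.986259	0.991524	0.0001	0.0001	0.0001	0.994
28S	2837	0.984671	0.997805	0.998705	0.0001	0.0001	0.0001	0.835
28S	2861	0.903707	0.910871	0.946508	0.0011	0.655	0.0017	0.0033
28S	2876	0.918528	0.81759	0.941158	0.0001	0.0001	0.0601	0.0001
28S	3701	0.895551	0.993059	0.990555	0.0001	0.0001	0.0001	0.912
28S	3724	0.991608	0.995094	0.992761	0.362	0.358	0.881	0.566
28S	3744	0.899003	0.810367	0.881939	0.0243	0.0312	0.818	0.0565
28S	3760	0.987395	1.0	0.997804	0.0793	0.0797	0.152	0.883
28S	3785	0.959855	0.995976	0.996038	0.00518	0.0081	0.0081	0.999
28S	3792	1.0	0.99989	0.999024	0.123	0.971	0.163	0.183
28S	3808	0.931588	0.985124	0.993318	0.000398	0.0012	0.0005	0.632
28S	3818	0.987092	0.998393	0.997999	0.00726	0.0102	0.0123	0.988
28S	3825	0.991377	0.998278	0.989947	0.102	0.23	0.927	0.105
28S	3830	0.956589	0.922148	0.96569	0.0001	0.0008	0.308	0.0001
28S	3841	0.995722	0.990531	0.98835	0.0444	0.144	0.0387	0.615
28S	3867	0.398386	0.863865	0.954061	0.0001	0.0001	0.0001	0.185
28S	3869	0.917171	0.935685	0.961319	0.143	0.642	0.131	0.394
28S	3887	0.978034	0.995064	0.995065	0.0137	0.0204	0.0204	0.999
28S	3899	0.981098	0.9843	0.990915	0.00142	0.229	0.0014	0.0095
28S	3925	0.936745	0.949838	0.982632	0.0001	0.12	0.0001	0.0007
28S	3944	0.43542	0.957662	0.971155	0.0001	0.0001	0.0001	0.922
28S	4042	0.827201	0.940962	0.991644	0.0001	0.0001	0.0001	0.0003
28S	4054	0.987696	0.987296	0.988987	0.907	0.995	0.951	0.904
28S	4196	0.998505	0.997973	0.997221	0.806	0.961	0.796	0.911
28S	4227	0.925469	0.996499	0.994203	0.0001	0.0001	0.0001	0.94
28S	4228	0.964003	0.981646	0.992173	0.0001	0.0011	0.0001	0.015
28S	4306	0.604514	0.993796	0.965317	0.0001	0.0001	0.0001	0.306
28S	4370	0.998482	0.939396	0.988933	0.00022	0.0004	0.541	0.0007
28S	4392	0.993777	0.998077	0.988699	0.463	0.848	0.796	0.433
28S	4456	0.993466	0.861522	0.958717	0.0001	0.0001	0.0339	0.0001
28S	4494	0.999014	0.999464	0.999342	0.541	0.523	0.7	0.942
28S	4498	0.991991	0.973779	0.971908	0.052	0.0866	0.0595	0.959
28S	4499	0.99781	0.993002	0.907781	0.00678	0.978	0.0134	0.012
28S	4523	0.997831	0.982592	0.975999	0.04	0.137	0.0346	0.589
28S	4536	0.995819	0.993318	0.999119	0.156	0.675	0.516	0.137
28S	4571	0.872787	0.868315	0.963485	0.0001	0.897	0.0001	0.0001
28S	4590	0.901049	0.968143	0.997735	0.0001	0.0001	0.0001	0.007
28S	4618	0.593665	0.855277	0.979272	0.000166	0.0018	0.0001	0.061
28S	4620	0.991591	0.736001	0.852558	0.000107	0.0001	0.0046	0.0081
28S	4623	0.97455	0.979873	0.913635	0.208	0.99	0.329	0.231
28S	4637	0.874646	0.523633	0.803216	0.0001	0.0001	0.0504	0.0001
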