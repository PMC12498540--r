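# Sites with significantly different 2'-O-methylation between WT and FMR1 KO ESCs
# mean MI per condition and unpaired two-tailed equal-variance t-test p-value
molecule_id	position	mi_wt	mi_ko	p_value
18S	116	0.8864	0.9655	0.00017305
18S	159	0.9833	0.9947	0.0458963
18S	172	0.7731	0.972	9.2952e-05
18S	174	0.6252	0.8848	0.0172618
18S	428	0.3384	0.5689	0.00790355
18S	468	0.9098	0.9919	0.03013167
18S	484	0.9223	0.981	0.01861479
18S	509	0.9679	0.9851	0.04543201
18S	576	0.8818	0.9908	0.02228417
18S	627	0.8857	0.9907	0.00191851
18S	644	0.9859	0.9956	0.00714317
18S	668	0.9025	0.9606	0.04182707
18S	867	0.7237	0.9843	0.00078173
18S	1288	0.9545	0.9685	0.01610787
18S	1328	0.9747	0.8895	0.00322142
18S	1383	0.9943	0.998	0.00902449
18S	1391	0.9981	0.9397	0.01181839
18S	1442	0.9353	0.9175	0.00311862
18S	1490	0.9992	0.9981	0.01562398
18S	1536	0.9388	0.1264	0.00028686
18S	1804	0.9155	0.9884	8.657100000000001e-05
28S	398	0.9978	0.9777	0.00698483
28S	400	0.9954	0.9853	0.00050524
28S	1326	0.9729	0.9857	0.04449346
28S	1340	0.8739	0.528	6.4053e-05
28S	1522	0.6632	0.9893	0.01578187
28S	1524	0.9336	0.9973	0.00019075
28S	1625	0.9884	0.9963	0.02518721
28S	1760	0.8988	0.992	0.00015771
28S	1881	0.5157	0.6317	0.01323617
28S	2351	0.9601	0.9977	0.00016025
28S	2363	0.9695	0.9973	0.00179803
28S	2364	0.9894	0.9963	0.00201424
28S	2422	0.912	0.9623	0.00548524
28S	2424	0.9685	0.9827	0.00087689
28S	2815	0.979	0.9907	0.04780965
28S	2824	0.5457	0.9483	0.00912978
28S	2837	0.9848	0.997	0.00727384
28S	2861	0.9038	0.9447	0.00043402
28S	3701	0.8956	0.9717	0.00195189
28S	3724	0.9916	0.9753	0.04275199
28S	3744	0.8988	0.7983	0.00356005
28S	3808	0.9316	0.9833	0.02257632
28S	3830	0.9567	0.9797	0.01623957
28S	3867	0.3985	0.8123	0.00467805
28S	3869	0.9173	0.778	0.03731292
28S	3887	0.9781	0.9993	0.02039052
28S	3925	0.9369	0.9753	0.01006758
28S	3944	0.4353	0.9223	0.0010103
28S	4042	0.8273	0.9603	0.00028329
28S	4227	0.9256	0.9933	0.00339875
28S	4228	0.9638	0.9967	0.00122037
28S	4306	0.6046	0.8987	8.234500000000001e-05
28S	4456	0.9934	0.9637	0.0022907
28S	4499	0.9979	0.9377	0.03272395
28S	4523	0.9978	0.9903	0.00519714
28S	4571	0.8729	0.936	0.03591427
28S	4590	0.901	0.9483	0.00595971
28S	4618	0.5938	0.9	0.01413858
28S	4620	0.9915	0.8897	0.00535085
28S	4637	0.8744	0.5803	0.00145973
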