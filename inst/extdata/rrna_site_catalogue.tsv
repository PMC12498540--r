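# Known 2'-O-methylation positions on human cytoplasmic rRNA
# Coordinates are 1-based nucleotide positions on the mature transcript
molecule_id	position	site_id	guide_snorna
18S	27	18S_27	
18S	99	18S_99	
18S	116	18S_116	
18S	121	18S_121	
18S	159	18S_159	
18S	166	18S_166	
18S	172	18S_172	
18S	174	18S_174	
18S	428	18S_428	
18S	436	18S_436	
18S	462	18S_462	
18S	468	18S_468	
18S	484	18S_484	
18S	509	18S_509	
18S	512	18S_512	
18S	517	18S_517	
18S	576	18S_576	
18S	590	18S_590	
18S	601	18S_601	
18S	627	18S_627	
18S	644	18S_644	
18S	668	18S_668	
18S	683	18S_683	
18S	797	18S_797	
18S	799	18S_799	
18S	867	18S_867	
18S	1031	18S_1031	
18S	1272	18S_1272	
18S	1288	18S_1288	
18S	1326	18S_1326	
18S	1328	18S_1328	
18S	1383	18S_1383	
18S	1391	18S_1391	
18S	1442	18S_1442	
18S	1447	18S_1447	
18S	1490	18S_1490	
18S	1536	18S_1536	
18S	1602	18S_1602	
18S	1668	18S_1668	
18S	1678	18S_1678	
18S	1703	18S_1703	
18S	1804	18S_1804	
28S	398	28S_398	
28S	400	28S_400	
28S	1316	28S_1316	
28S	1326	28S_1326	
28S	1340	28S_1340	
28S	1522	28S_1522	
28S	1524	28S_1524	
28S	1534	28S_1534	
28S	1625	28S_1625	
28S	1760	28S_1760	
28S	1871	28S_1871	
28S	1881	28S_1881	
28S	2351	28S_2351	
28S	2363	28S_2363	
28S	2364	28S_2364	
28S	2365	28S_2365	
28S	2401	28S_2401	
28S	2415	28S_2415	
28S	2422	28S_2422	
28S	2424	28S_2424	
28S	2787	28S_2787	
28S	2804	28S_2804	
28S	2815	28S_2815	
28S	2824	28S_2824	
28S	2837	28S_2837	
28S	2861	28S_2861	
28S	2876	28S_2876	
28S	3701	28S_3701	
28S	3724	28S_3724	
28S	3744	28S_3744	
28S	3760	28S_3760	
28S	3785	28S_3785	
28S	3792	28S_3792	
28S	3808	28S_3808	
28S	3818	28S_3818	
28S	3825	28S_3825	
28S	3830	28S_3830	
28S	3841	28S_3841	
28S	3867	28S_3867	
28S	3869	28S_3869	
28S	3887	28S_3887	
28S	3899	28S_3899	
28S	3925	28S_3925	
28S	3944	28S_3944	
28S	4042	28S_4042	
28S	4054	28S_4054	
28S	4196	28S_4196	
28S	4227	28S_4227	
28S	4228	28S_4228	
28S	4306	28S_4306	
28S	4370	28S_4370	
28S	4392	28S_4392	
28S	4456	28S_4456	
28S	4494	28S_4494	
28S	4498	28S_4498	
28S	4499	28S_4499	
28S	4523	28S_4523	
28S	4536	28S_4536	
28S	4571	28S_4571	
28S	4590	28S_4590	
28S	4618	28S_4618	
28S	4620	28S_4620	
28S	4623	28S_4623	
28S	4637	28S_4637	
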