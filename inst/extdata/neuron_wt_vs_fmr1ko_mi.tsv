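# Sites with significantly different 2'-O-methylation between WT and FMR1 KO neurons
# mean MI per condition and unpaired two-tailed equal-variance t-test p-value
molecule_id	position	mi_wt	mi_ko	p_value
18S	99	0.9925	0.9978	0.00376031
18S	172	0.9858	0.995	0.00212042
18S	436	0.9385	0.9685	0.04156871
18S	627	0.9938	0.9973	0.02739604
18S	799	0.974	0.9953	0.00414657
18S	1804	0.9965	0.9983	0.04479426
28S	1871	0.9993	0.9968	0.03076601
28S	1881	0.9338	0.8988	0.0017439
28S	2861	0.9463	0.9235	0.04291374
28S	3899	0.991	0.9955	0.00692005
28S	4054	0.989	0.9773	0.03487105
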