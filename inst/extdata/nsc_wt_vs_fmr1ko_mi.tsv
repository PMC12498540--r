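# Sites with significantly different 2'-O-methylation between WT and FMR1 KO NSCs
# mean MI per condition and unpaired two-tailed equal-variance t-test p-value
molecule_id	position	mi_wt	mi_ko	p_value
18S	99	0.9947	0.9967	0.01071522
18S	116	0.9137	0.96	0.0007347
18S	159	0.9754	0.9814	0.02030539
18S	166	0.9902	0.9943	0.04352719
18S	172	0.9863	0.99	0.02795788
18S	428	0.7624	0.8545	0.00086674
18S	512	0.9785	0.9842	0.01070892
28S	398	0.9977	0.9949	0.00781102
28S	1326	0.9886	0.9921	0.0102442
28S	2415	0.9182	0.8871	0.00247807
28S	2861	0.9109	0.8917	0.00568395
28S	3760	1.0	0.9976	0.03563853
28S	4618	0.8553	0.8221	0.01716329
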