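stratum	test	statistic	df	p_value	status	n
all	RoP cis	40.68444974	1	1.789052185e-10	ok	24
all	RoP trans	7.382910378	1	0.006584652878	ok	24
all	genotype interaction (4 df)	28.28674531	3	3.161943608e-06	ok	24
all	saturated (5 df)	58.53897918	4	5.880676382e-12	ok	24
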