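sample_id	expr	rin	sex
S01	0.8901	6.19	F
S02	1.2182	6.46	F
S03	1.128	7.66	F
S04	3.0085	8.89	F
S05	1.0339	6.72	F
S06	2.1276	6.18	F
S07	1.7059	6.24	F
S08	0.9736	6.27	F
S09	1.0292	8.9	F
S10	1.2883	6.84	F
S11	1.3117	8.7	F
S12	0.9514	7.64	F
S13	0.9719	6.03	M
S14	0.9935	8.93	M
S15	1.056	6.87	M
S16	2.018	6.87	M
S17	1.2049	7.14	M
S18	1.4215	8.81	M
S19	1.0309	6.68	M
S20	2.0826	8.8	M
S21	0.9492	7.67	M
S22	1.3039	8.12	M
S23	1.3563	6.87	M
S24	0.8242	8.2	M
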