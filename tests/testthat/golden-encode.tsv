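sample_id	GA	DA	GB	DB	CisAB	CisaB	CisAb	Cisab	TransAB	TransaB	TransAb	Transab
S01	0	0	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
S02	1	1	0	0	0	0	1	1	0	0	1	1
S03	0	0	0	0	0	0	0	2	0	0	0	2
S04	2	0	2	0	2	0	0	0	2	0	0	0
S05	0	0	1	1	0	1	0	1	0	1	0	1
S06	1	1	1	1	NA	NA	NA	NA	NA	NA	NA	NA
S07	1	1	1	1	1	0	0	1	0	1	1	0
S08	0	0	0	0	0	0	0	2	0	0	0	2
S09	1	1	0	0	0	0	1	1	0	0	1	1
S10	1	1	1	1	0	1	1	0	1	0	0	1
S11	1	1	2	0	1	1	0	0	1	1	0	0
S12	0	0	0	0	0	0	0	2	0	0	0	2
S13	0	0	0	0	0	0	0	2	0	0	0	2
S14	2	0	0	0	0	0	2	0	0	0	2	0
S15	0	0	0	0	0	0	0	2	0	0	0	2
S16	2	0	1	1	1	0	1	0	1	0	1	0
S17	0	0	1	1	0	1	0	1	0	1	0	1
S18	1	1	1	1	0	1	1	0	1	0	0	1
S19	0	0	1	1	0	1	0	1	0	1	0	1
S20	1	1	1	1	1	0	0	1	0	1	1	0
S21	1	1	0	0	0	0	1	1	0	0	1	1
S22	0	0	0	0	0	0	0	2	0	0	0	2
S23	1	1	0	0	0	0	1	1	0	0	1	1
S24	1	1	0	0	0	0	1	1	0	0	1	1
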