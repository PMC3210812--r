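gene_id	symbol	species	source	record_status	is_kinase
900001	DAPK1	human	protoarray	annotated	1
900002	PAK1	human	protoarray	annotated	1
900003	CDK2	human	protoarray	annotated	1
900004	PLK3	human	protoarray	annotated	1
900005	AURKB	human	protoarray	annotated	1
900006	AURKC	human	protoarray	annotated	1
900007	MAPKAPK3	human	protoarray	annotated	1
900008	DYRK3	human	protoarray	annotated	1
900009	EPHA8	human	protoarray	annotated	1
900010	EPHB3	human	protoarray	annotated	1
900011	TRIB1	human	protoarray	annotated	1
900012	DEPDC6	human	protoarray	annotated	0
900013	DDX17	human	protoarray	annotated	0
900014	MPG	human	protoarray	annotated	0
900015	SNCB	human	protoarray	annotated	0
900016	LST1	human	protoarray	annotated	0
900017	NKD2	human	protoarray	annotated	0
900018	RASL11B	human	protoarray	annotated	0
900019	KCNA4	human	protoarray	annotated	0
900020	KCNAB1	human	protoarray	annotated	0
900021	KCNAB2	human	protoarray	annotated	0
900022	ARPP19	human	protoarray	annotated	0
900023	SCLT1	human	protoarray	annotated	0
900024	C1ORF183	human	protoarray	annotated	0
900025	CAMK2N2	human	protoarray	annotated	0
900026	MUSTN1	human	protoarray	annotated	0
900027	PLEKHG5	human	protoarray	annotated	0
900028	PPID	human	protoarray	annotated	0
900029	MGC18299	human	protoarray	annotated	0
900030	MRPS24	human	protoarray	annotated	0
900031	ZADH2	human	protoarray	annotated	0
900032	KIAA1598	human	protoarray	annotated	0
900033	SYNHIT01	human	protoarray	annotated	0
900034	SYNHIT02	human	protoarray	annotated	0
900035	SYNHIT03	human	protoarray	annotated	0
900036	SYNHIT04	human	protoarray	annotated	0
900037	SYNHIT05	human	protoarray	annotated	0
900038	SYNHIT06	human	protoarray	annotated	0
900039	SYNHIT07	human	protoarray	annotated	0
900040	SYNHIT08	human	protoarray	annotated	0
900041	SYNHIT09	human	protoarray	annotated	0
900042	SYNHIT10	human	protoarray	annotated	0
900043	SYNHIT11	human	protoarray	annotated	0
900044	SYNHIT12	human	protoarray	annotated	0
900045	SYNHIT13	human	protoarray	annotated	0
900046	SYNHIT14	human	protoarray	annotated	0
900047	SYNHIT15	human	protoarray	annotated	0
900048	SYNHIT16	human	protoarray	annotated	0
900049	SYNHIT17	human	protoarray	annotated	0
900050	SYNHIT18	human	protoarray	annotated	0
900051	SYNHIT19	human	protoarray	annotated	0
900052	SYNHIT20	human	protoarray	annotated	0
900053	SYNHIT21	human	protoarray	annotated	0
900054	SYNUTR1	human	protoarray	utr3	0
900055	SYNUTR2	human	protoarray	utr3	0
900056	SYNUTR3	human	protoarray	utr3	0
900057	SYNUTR4	human	protoarray	utr3	0
900058	SYNWDR1	human	protoarray	withdrawn	0
900059	SYNWDR2	human	protoarray	withdrawn	0
900060	SYNWDR3	human	protoarray	withdrawn	0
900061	SYNNC1	human	protoarray	suppressed_noncoding	0
900062	SYNNMD1	human	protoarray	nmd_candidate	0
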