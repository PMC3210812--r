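protein	array_cterm	wildtype_cterm
AMMECR1L	RSV RSR SPH ESV*	Not translated to protein
AURKB	RVL PPS ALQ SVA*	WT
AURKC	GRA DPA FLY KVV*	RRV LPP CAQ MAS*
C1ORF183	PSG FDI NTA VWV*	WT
CAMK2N2	LKG MGE KPP SGV*	WT
DAPK1	GRA DPA FLY KVV*	TSY NSI SSV VSR*
DEPDC6	TIV MEV MEE LEC*	WT
EBF4	SPA RGL QGL AYS*	Not translated to protein
EPHB3	GRA DPA FLY KVV*	RLQ MNQ TLP VQV*
IMAGE:4829245	DKA MLE LGP HIC*	WT
KIAA1598	IEN VRE TDS SNC*	AVD ELK GIL ASQ*
MGC18299	NKQ NYT KPT TSV*	WT
MRPS24	QTV PSK VVY KYL*	WT
MUSTN1	KPK AGP TKS VFG*	WT
NKD2	WPG PFP SGL VAV*	WT
PLEKHG5	LLL NST LTA SEV*	WT
PPID	DKE KAV YAK MFA*	WT
RASL11B	ALS AKV RTV TSV*	WT
SCLT1	GEL NGQ LKY YQA*	WT
SNCB	PQE EYQ EYE PEA*	WT
ZADH2	VVE LPH SVN SKL*	WT
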