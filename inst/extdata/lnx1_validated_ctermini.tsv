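protein	gene_id	cterm	source	mf_cluster
ARVCF	421	GDAKPQPVDSWV	pdz_peptide_screen	1
claudin-1	9076	PAPSSGKDYV	pdz_peptide_screen	1
Claudin-3	1365	GTGYDRKDYV	pdz_peptide_screen	1
AURKB	9212	RVLPPSALQSVA	protoarray	4
CDK2	1017	QDVTKPVPHLRL	protoarray	4
MAPKAPK3	7867	GSSSASQGCNNQ	protoarray	4
PAK6	56924	QLYRKQTSTC	pdz_peptide_screen	4
PBK	55872	HIVEALETDV	pdz_peptide_screen	4
TYK2	7297	GQAPSVFSVC	pdz_peptide_screen	4
PKC-alpha1	5578	PQFVHPILQSAV	peptide_profile	4
KCNA4	3739	NCSNAKAVETDV	pdz_peptide_screen	7
PLEKHG5	57449	LLLNSTLTASEV	protoarray	9
RASL11B	65997	ALSAKVRTVTSV	protoarray	
CAMK2N2	94032	LKGMGEKPPSGV	protoarray	
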