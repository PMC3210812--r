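protein	gene_id	cterm	source
WWP1	11059	FAIEETEGFGQE	y2h_this_study
NG23	401251	GCTKGPRGPTRV	y2h_this_study
PRA1	10567	AVDGEELQMEPV	y2h_this_study
TP14C	51522	AKVGVSMFNRPH	y2h_this_study
WAC	51322	LEKLKNQNSFMV	y2h_this_study
Syntaxin5	6811	IVFFIIFVVFLA	y2h_this_study
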